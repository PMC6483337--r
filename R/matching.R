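# Two-dimensional matching: four genomic-proximity categories refined
# by case-level phenotype similarity, pruned to a configurable top-N.

PROXIMITY_CATEGORIES <- c(IDENTICAL = 1L, SAME_POSITION = 2L,
                          SAME_CODON = 3L, SAME_GENE = 4L)

#' Genomic proximity category of two annotated variants
#'
#' Categories in decreasing match strength: `IDENTICAL` (same
#' chrom/pos/ref/alt), `SAME_POSITION` (same chrom and pos, different
#' alleles), `SAME_CODON` (some transcript shared by both variants'
#' filter-passing hits assigns them equal codon ordinals), `SAME_GENE`
#' (filter-passing gene sets intersect). Returns `NULL` when none
#' applies. Both variants must be normalized, annotated, filtered and
#' on the same assembly.
#'
#' @param a,b `annotated_variant` objects with filters applied.
#' @return List with `category` (name) and `rank` (1-4), or `NULL`.
#' @export
proximity_category <- function(a, b) {
  va <- a$variant; vb <- b$variant
  if (va$assembly != vb$assembly)
    stop("cannot compare variants on different assemblies: ",
         va$assembly, " vs ", vb$assembly)
  cat_name <- NULL
  if (va$chrom == vb$chrom && va$pos == vb$pos &&
      va$ref == vb$ref && va$alt == vb$alt) {
    cat_name <- "IDENTICAL"
  } else if (va$chrom == vb$chrom && va$pos == vb$pos) {
    cat_name <- "SAME_POSITION"
  } else {
    ha <- a$transcript_hits[a$transcript_hits$pass %in% TRUE, , drop = FALSE]
    hb <- b$transcript_hits[b$transcript_hits$pass %in% TRUE, , drop = FALSE]
    shared <- intersect(ha$transcript_id, hb$transcript_id)
    same_codon <- FALSE
    for (t in shared) {
      ca <- ha$codon_index[ha$transcript_id == t]
      cb <- hb$codon_index[hb$transcript_id == t]
      if (length(ca) && length(cb) && !is.na(ca[1]) && !is.na(cb[1]) &&
          ca[1] == cb[1]) { same_codon <- TRUE; break }
    }
    if (same_codon) cat_name <- "SAME_CODON"
    else if (length(intersect(ha$gene_id, hb$gene_id))) cat_name <- "SAME_GENE"
  }
  if (is.null(cat_name)) return(NULL)
  list(category = cat_name, rank = unname(PROXIMITY_CATEGORIES[cat_name]))
}

empty_match_records <- function() {
  data.frame(query_case_id = character(), query_variant = character(),
             hit_case_id = character(), hit_variant = character(),
             hit_owner = character(), category = character(),
             rank = integer(), similarity = numeric(),
             same_owner = logical(), hit_seq = integer(),
             stringsAsFactors = FALSE)
}

#' Rank candidate match records
#'
#' Deterministic global ordering: proximity category rank ascending
#' (category dominates), phenotype similarity descending within a
#' category, then hit-case submission order and hit-case id as
#' tie-breaks.
#'
#' @param records Match-record data frame (see [match_case()]).
#' @return The same data frame, reordered, with `rank_order` set to
#'   1..n.
#' @export
rank_matches <- function(records) {
  if (!nrow(records)) { records$rank_order <- integer(); return(records) }
  o <- order(records$rank, -records$similarity, records$hit_seq,
             records$hit_case_id, records$query_variant)
  records <- records[o, , drop = FALSE]
  records$rank_order <- seq_len(nrow(records))
  rownames(records) <- NULL
  records
}

#' Match one case against a set of stored cases
#'
#' Forms candidates over all filter-passing variant pairs between the
#' query case and every other PROCESSED, non-retracted case; keeps at
#' most one record per (query variant, hit case) — the lowest category
#' rank, ties resolved toward higher similarity; attaches the case-pair
#' phenotype similarity (computed once per pair over the full
#' profiles); ranks with [rank_matches()] and truncates to `top_n`.
#'
#' @param query A `case_record` (processed).
#' @param cases List of stored `case_record`s (may include the query
#'   itself; self-matches are excluded by case id).
#' @param cache A `path_cache` for phenotype similarity.
#' @param top_n Maximum number of reported hits (default 5).
#' @return Ranked match-record data frame, at most `top_n` rows.
#' @export
match_case <- function(query, cases, cache, top_n = 5L) {
  recs <- list()
  qvars <- Filter(function(av) isTRUE(av$passed_filters), query$variants)
  for (other in cases) {
    if (other$case_id == query$case_id) next
    if (!identical(other$status, "PROCESSED")) next
    sim <- NULL
    for (qi in seq_along(qvars)) {
      best <- NULL
      for (hv in other$variants) {
        if (!isTRUE(hv$passed_filters)) next
        pc <- proximity_category(qvars[[qi]], hv)
        if (is.null(pc)) next
        if (is.null(best) || pc$rank < best$rank) {
          best <- list(rank = pc$rank, category = pc$category, hv = hv)
        }
      }
      if (is.null(best)) next
      if (is.null(sim))
        sim <- case_similarity(cache, query$profile, other$profile)
      recs[[length(recs) + 1L]] <- data.frame(
        query_case_id = query$case_id,
        query_variant = variant_label(qvars[[qi]]$variant),
        hit_case_id = other$case_id,
        hit_variant = variant_label(best$hv$variant),
        hit_owner = other$owner,
        category = best$category, rank = best$rank,
        similarity = sim,
        same_owner = identical(other$owner, query$owner),
        hit_seq = other$submitted_seq,
        stringsAsFactors = FALSE)
    }
  }
  out <- if (length(recs)) do.call(rbind, recs) else empty_match_records()
  out <- rank_matches(out)
  utils::head(out, top_n)
}

#' Build give-and-take match reports
#'
#' One report goes to the owner of the newly submitted case with all
#' its matches; one report goes to each distinct owner of a hit case,
#' containing the records that involve their case(s) with the roles
#' swapped (their case appears as the query). Two hit cases with the
#' same owner yield one combined report.
#'
#' @param new_case The freshly processed `case_record`.
#' @param matches Ranked match-record data frame from [match_case()].
#' @param suppress_empty Drop the submitter report when no matches
#'   were found.
#' @return List of `match_report` objects (`recipient`, `case_id`,
#'   `matches`).
#' @export
build_match_reports <- function(new_case, matches, suppress_empty = FALSE) {
  reports <- list()
  if (nrow(matches) || !suppress_empty) {
    reports[[1]] <- structure(
      list(recipient = new_case$owner, case_id = new_case$case_id,
           matches = matches),
      class = "match_report")
  }
  if (nrow(matches)) {
    for (ow in unique(matches$hit_owner)) {
      theirs <- matches[matches$hit_owner == ow, , drop = FALSE]
      swapped <- data.frame(
        query_case_id = theirs$hit_case_id,
        query_variant = theirs$hit_variant,
        hit_case_id = theirs$query_case_id,
        hit_variant = theirs$query_variant,
        hit_owner = new_case$owner,
        category = theirs$category, rank = theirs$rank,
        similarity = theirs$similarity,
        same_owner = theirs$same_owner,
        hit_seq = new_case$submitted_seq,
        stringsAsFactors = FALSE)
      swapped <- rank_matches(swapped)
      reports[[length(reports) + 1L]] <- structure(
        list(recipient = ow,
             case_id = paste(sort(unique(theirs$hit_case_id)),
                             collapse = ","),
             matches = swapped),
        class = "match_report")
    }
  }
  reports
}

#' Render a match report as TSV text
#'
#' Columns: rank, category, similarity, query_variant, hit_variant,
#' hit_case, owner, same_owner.
#'
#' @param report A `match_report`.
#' @return Character vector of TSV lines (header first).
#' @export
format_report_tsv <- function(report) {
  hdr <- paste("rank", "category", "similarity", "query_variant",
               "hit_variant", "hit_case", "owner", "same_owner", sep = "\t")
  m <- report$matches
  if (!nrow(m)) return(hdr)
  c(hdr, paste(m$rank_order, m$category, format(m$similarity, digits = 6),
               m$query_variant, m$hit_variant, m$hit_case_id, m$hit_owner,
               tolower(m$same_owner), sep = "\t"))
}

#' @export
print.match_report <- function(x, ...) {
  cat("Match report for", x$recipient, "on case", x$case_id, "-",
      nrow(x$matches), "match(es)\n")
  if (nrow(x$matches)) writeLines(format_report_tsv(x))
  invisible(x)
}
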