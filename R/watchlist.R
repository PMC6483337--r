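# The watch list: persistent case store and the submission pipeline
# (validate -> extract -> normalize -> convert -> annotate -> beacon ->
# filter -> match), with a per-submission processing trace.
#
# Stages are pure per-variant functions executed sequentially; after
# validation no stage can abort the whole submission — per-variant
# failures land in the trace for submitter follow-up. Timestamps are
# logical submission sequence numbers so that replaying the same
# submissions yields byte-identical stores and reports.

#' Create a watch list
#'
#' @param ontology An `ontology` (see [parse_obo()]).
#' @param cache A `path_cache` for the ontology; built on the fly when
#'   omitted.
#' @param genome `ref_genome` of the internal coordinate assembly
#'   (the assembly every stored variant is converted to).
#' @param models `gene_models` for annotation.
#' @param known Optional `known_store` for beacon-style checks.
#' @param maf_table Optional named numeric MAF vector
#'   (see [read_maf_vcf()]).
#' @param filter_cfg A `filter_config`.
#' @param top_n Maximum number of reported top hits (default 5).
#' @param accepted_assemblies Assembly labels accepted at submission;
#'   defaults to the internal assembly only.
#' @param mappings List of `assembly_mapping` providers for converting
#'   accepted assemblies to the internal one.
#' @param suppress_empty_reports Drop submitter reports with no matches.
#' @return Object of class `watchlist` (an environment).
#' @export
watchlist <- function(ontology, genome, models, cache = NULL, known = NULL,
                      maf_table = NULL, filter_cfg = filter_config(),
                      top_n = 5L, accepted_assemblies = genome$assembly,
                      mappings = list(), suppress_empty_reports = FALSE) {
  if (is.null(cache)) cache <- precompute_path_cache(ontology)
  wl <- new.env(parent = emptyenv())
  wl$ont <- ontology
  wl$cache <- cache
  wl$genome <- genome
  wl$models <- models
  wl$known <- known
  wl$maf_table <- maf_table
  wl$filter_cfg <- filter_cfg
  wl$top_n <- as.integer(top_n)
  wl$accepted_assemblies <- accepted_assemblies
  wl$mappings <- mappings
  wl$suppress_empty_reports <- suppress_empty_reports
  wl$cases <- list()
  wl$seq <- 0L
  class(wl) <- "watchlist"
  wl
}

#' @export
print.watchlist <- function(x, ...) {
  st <- vapply(x$cases, function(cs) cs$status, character(1))
  cat("Watch list:", length(x$cases), "case(s)",
      if (length(st)) paste0("(", sum(st == "PROCESSED"), " processed)")
      else "", "\n")
  invisible(x)
}

#' Load a known-variant store from VCF
#'
#' A local stand-in for a beacon network: the set of already-publicized
#' alleles, normalized with the same left normalization as submissions
#' so representation differences cannot hide a hit.
#'
#' @param x VCF path or lines.
#' @param genome `ref_genome` the store coordinates refer to.
#' @param source_label Free-text provenance label.
#' @return Object of class `known_store`.
#' @export
load_known_variants <- function(x, genome, source_label = "local") {
  r <- read_vcf(x, genome$assembly)
  v <- left_normalize(r$variants, genome)
  structure(list(keys = unique(variant_key(v)), source_label = source_label),
            class = "known_store")
}

#' Beacon-style allele presence check
#'
#' Exact yes/no membership of a normalized variant in the known-variant
#' store. A hit informs the submitter that the allele has already been
#' publicized; it does not remove the variant from matching.
#'
#' @param v One-row variant data frame (normalized).
#' @param store A `known_store` (or NULL, in which case always FALSE).
#' @return Logical.
#' @export
beacon_check <- function(v, store) {
  if (is.null(store)) return(FALSE)
  variant_key(v) %in% store$keys
}

#' Submit a case to the watch list
#'
#' Runs the full processing pipeline: submission validation, variant
#' extraction (generic records, VCF, genomic HGVS), left normalization,
#' assembly conversion, annotation, beacon check, matchability filters;
#' then matches the case against every previously processed case and
#' builds give-and-take reports for the submitter and for the owners of
#' all hit cases. The case joins the watch list for future submissions.
#' Per-variant failures after validation never abort the submission;
#' each is recorded in the processing trace.
#'
#' @param wl A `watchlist`.
#' @param raw Submission list: `owner`, `assembly`, at least one of
#'   `variants` / `vcf` / `hgvs`, `hpo_terms`, optional
#'   `mode_of_inheritance` and `age_of_onset`.
#' @return List with `case` (a `case_record`, status PROCESSED or
#'   FAILED) and `reports` (list of `match_report`).
#' @export
submit_case <- function(wl, raw) {
  seq_no <- wl$seq + 1L
  case_id <- sprintf("CASE-%06d", seq_no)
  trace <- empty_trace()
  note <- function(stage, record, reason)
    trace <<- rbind(trace, new_trace_entry(stage, record, reason, seq_no))

  vr <- validate_submission(raw, wl$ont, wl$genome, wl$accepted_assemblies)
  for (k in seq_len(nrow(vr$rejected)))
    note("validate", vr$rejected$record[k], vr$rejected$reason[k])
  for (r in vr$reasons) note("validate", "<submission>", r)

  cs <- structure(list(
    case_id = case_id, owner = raw$owner %||% "unknown",
    variants = list(), profile = vr$terms,
    mode_of_inheritance = raw$mode_of_inheritance %||% NA_character_,
    age_of_onset = raw$age_of_onset %||% NA_character_,
    assembly_submitted = raw$assembly %||% NA_character_,
    status = "RECEIVED", trace = trace,
    submitted_seq = seq_no, match_counts = integer()),
    class = "case_record")

  if (!vr$ok) {
    cs$status <- "FAILED"
    cs$trace <- trace
    wl$cases[[case_id]] <- cs
    wl$seq <- seq_no
    return(list(case = cs, reports = list()))
  }

  annotated <- list()
  for (i in seq_len(nrow(vr$accepted))) {
    v <- vr$accepted[i, ]
    lbl <- variant_label(v)
    v <- tryCatch(left_normalize(v, wl$genome), error = function(e) e)
    if (inherits(v, "error")) { note("normalize", lbl, conditionMessage(v)); next }
    if (v$assembly != wl$genome$assembly) {
      v <- tryCatch(convert_assembly(v, wl$genome, wl$mappings),
                    error = function(e) e)
      if (inherits(v, "error")) { note("convert", lbl, conditionMessage(v)); next }
      v <- tryCatch(left_normalize(v, wl$genome), error = function(e) e)
      if (inherits(v, "error")) { note("convert", lbl, conditionMessage(v)); next }
    }
    key <- variant_key(v)
    if (key %in% vapply(annotated, function(a) variant_key(a$variant),
                        character(1))) {
      note("extract", variant_label(v), "duplicate variant")
      next
    }
    av <- annotate_variant(v, wl$models, wl$genome, wl$maf_table)
    if (beacon_check(v, wl$known)) {
      av$beacon_hit <- TRUE
      note("beacon", variant_label(v), "already publicized")
    }
    av <- apply_filters(av, wl$filter_cfg)
    if (!av$passed_filters)
      note("filter", variant_label(v),
           paste0("excluded from matching: ", av$filter_reason))
    annotated[[length(annotated) + 1L]] <- av
  }

  if (!length(annotated)) {
    note("extract", "<submission>", "no variants survived processing")
    cs$status <- "FAILED"
    cs$trace <- trace
    wl$cases[[case_id]] <- cs
    wl$seq <- seq_no
    return(list(case = cs, reports = list()))
  }
  if (!any(vapply(annotated, function(a) isTRUE(a$passed_filters),
                  logical(1))))
    note("filter", "<submission>", "no matchable variants")

  cs$variants <- annotated
  cs$status <- "PROCESSED"
  cs$trace <- trace
  cs$match_counts <- stats::setNames(
    integer(length(annotated)),
    vapply(annotated, function(a) variant_label(a$variant), character(1)))

  matches <- match_case(cs, wl$cases, wl$cache, wl$top_n)
  reports <- build_match_reports(cs, matches, wl$suppress_empty_reports)

  # per-variant match counters, both sides of the give-and-take
  for (k in seq_len(nrow(matches))) {
    qv <- matches$query_variant[k]
    cs$match_counts[qv] <- cs$match_counts[qv] + 1L
    hc <- matches$hit_case_id[k]
    hv <- matches$hit_variant[k]
    if (hv %in% names(wl$cases[[hc]]$match_counts))
      wl$cases[[hc]]$match_counts[hv] <- wl$cases[[hc]]$match_counts[hv] + 1L
  }

  wl$cases[[case_id]] <- cs
  wl$seq <- seq_no
  list(case = cs, reports = reports)
}

#' Retract a case from the watch list
#'
#' A retracted case never appears in future match results; historical
#' reports are untouched.
#'
#' @param wl A `watchlist`.
#' @param case_id Case identifier.
#' @param on_double `"error"` (default) to reject retracting an
#'   already-retracted case, `"noop"` to ignore it.
#' @return The updated `case_record`, invisibly.
#' @export
retract_case <- function(wl, case_id, on_double = c("error", "noop")) {
  on_double <- match.arg(on_double)
  cs <- wl$cases[[case_id]]
  if (is.null(cs)) stop("unknown case: ", case_id)
  if (cs$status == "RETRACTED") {
    if (on_double == "error") stop("case already retracted: ", case_id)
    return(invisible(cs))
  }
  cs$status <- "RETRACTED"
  cs$trace <- rbind(cs$trace,
                    new_trace_entry("retract", case_id, "retracted by owner",
                                    wl$seq))
  wl$cases[[case_id]] <- cs
  invisible(cs)
}

#' Status summary of a case
#'
#' @param wl A `watchlist`.
#' @param case_id Case identifier.
#' @return List with `case_id`, `status`, `owner`, `variants` (data
#'   frame: variant, passed_filters, beacon_hit, match_count) and
#'   `trace`.
#' @export
case_status <- function(wl, case_id) {
  cs <- wl$cases[[case_id]]
  if (is.null(cs)) stop("unknown case: ", case_id)
  vdf <- if (length(cs$variants)) data.frame(
    variant = vapply(cs$variants, function(a) variant_label(a$variant),
                     character(1)),
    passed_filters = vapply(cs$variants, function(a)
      isTRUE(a$passed_filters), logical(1)),
    beacon_hit = vapply(cs$variants, function(a)
      isTRUE(a$beacon_hit), logical(1)),
    stringsAsFactors = FALSE)
  else data.frame(variant = character(), passed_filters = logical(),
                  beacon_hit = logical(), stringsAsFactors = FALSE)
  vdf$match_count <- unname(cs$match_counts[vdf$variant])
  vdf$match_count[is.na(vdf$match_count)] <- 0L
  list(case_id = cs$case_id, status = cs$status, owner = cs$owner,
       variants = vdf, trace = cs$trace)
}

#' Re-run matching over the whole watch list
#'
#' Recomputes every processed case's matches (e.g. after a filter or
#' ontology change) in submission order, rebuilding reports and
#' per-variant match counters from scratch.
#'
#' @param wl A `watchlist`.
#' @return Named list (by case id) of report lists.
#' @export
rescan <- function(wl) {
  ids <- names(wl$cases)
  ids <- ids[order(vapply(wl$cases, function(cs) cs$submitted_seq,
                          integer(1)))]
  for (id in ids)
    wl$cases[[id]]$match_counts[] <- 0L
  out <- list()
  for (id in ids) {
    cs <- wl$cases[[id]]
    if (cs$status != "PROCESSED") next
    earlier <- Filter(function(o) o$submitted_seq < cs$submitted_seq,
                      wl$cases)
    matches <- match_case(cs, earlier, wl$cache, wl$top_n)
    out[[id]] <- build_match_reports(cs, matches, wl$suppress_empty_reports)
    for (k in seq_len(nrow(matches))) {
      qv <- matches$query_variant[k]
      wl$cases[[id]]$match_counts[qv] <-
        wl$cases[[id]]$match_counts[qv] + 1L
      hc <- matches$hit_case_id[k]; hv <- matches$hit_variant[k]
      if (hv %in% names(wl$cases[[hc]]$match_counts))
        wl$cases[[hc]]$match_counts[hv] <-
          wl$cases[[hc]]$match_counts[hv] + 1L
    }
  }
  out
}

.case_to_list <- function(cs) {
  list(
    case_id = cs$case_id,
    owner = cs$owner,
    assembly_submitted = cs$assembly_submitted,
    status = cs$status,
    submitted_seq = cs$submitted_seq,
    profile = as.list(cs$profile),
    mode_of_inheritance = cs$mode_of_inheritance,
    age_of_onset = cs$age_of_onset,
    variants = lapply(cs$variants, function(a) list(
      variant = as.list(a$variant),
      gene_ids = as.list(a$gene_ids),
      transcript_hits = a$transcript_hits,
      maf = a$maf,
      passed_filters = a$passed_filters,
      beacon_hit = a$beacon_hit,
      filter_reason = a$filter_reason)),
    match_counts = as.list(cs$match_counts),
    trace = cs$trace)
}

#' Export / import the watch list store
#'
#' `export_store` writes one JSON object per case (JSON lines,
#' deterministic field order) plus a site-only VCF of all stored
#' variants; `import_store` rebuilds the cases of a watch list from
#' such a JSON-lines file.
#'
#' @param wl A `watchlist`.
#' @param jsonl_path Cases file (JSON lines).
#' @param vcf_path Optional VCF export of stored variants.
#' @return `export_store`: the jsonl path, invisibly. `import_store`:
#'   the `watchlist`, invisibly.
#' @export
export_store <- function(wl, jsonl_path, vcf_path = NULL) {
  ids <- names(wl$cases)
  ids <- ids[order(vapply(wl$cases, function(cs) cs$submitted_seq,
                          integer(1)))]
  lines <- vapply(ids, function(id)
    as.character(jsonlite::toJSON(.case_to_list(wl$cases[[id]]),
                                  auto_unbox = TRUE, digits = NA,
                                  na = "null")),
    character(1))
  writeLines(lines, jsonl_path)
  if (!is.null(vcf_path)) {
    vs <- list()
    for (id in ids) for (a in wl$cases[[id]]$variants)
      vs[[length(vs) + 1L]] <- a$variant
    vdf <- if (length(vs)) unique(do.call(rbind, vs)) else empty_variants()
    vdf <- vdf[order(vdf$chrom, vdf$pos, vdf$ref, vdf$alt), , drop = FALSE]
    write_vcf(vdf, vcf_path)
  }
  invisible(jsonl_path)
}

#' @rdname export_store
#' @export
import_store <- function(wl, jsonl_path) {
  lines <- readLines(jsonl_path, warn = FALSE)
  for (line in lines[nzchar(lines)]) {
    o <- jsonlite::fromJSON(line, simplifyDataFrame = FALSE)
    th_cols <- c("transcript_id", "gene_id", "region", "codon_index",
                 "consequence", "impact", "biotype", "canonical", "pass")
    variants <- lapply(o$variants, function(a) {
      th <- if (length(a$transcript_hits)) do.call(rbind, lapply(
        a$transcript_hits, function(h) {
          h <- h[th_cols]
          h <- lapply(h, function(x) if (is.null(x)) NA else x)
          as.data.frame(h, stringsAsFactors = FALSE)
        }))
      else empty_transcript_hits()
      th$codon_index <- as.integer(th$codon_index)
      structure(list(
        variant = variant(a$variant$assembly, a$variant$chrom,
                          a$variant$pos, a$variant$ref, a$variant$alt),
        gene_ids = as.character(unlist(a$gene_ids)),
        transcript_hits = th,
        maf = if (is.null(a$maf)) NA_real_ else a$maf,
        passed_filters = isTRUE(a$passed_filters),
        beacon_hit = isTRUE(a$beacon_hit),
        filter_reason = if (is.null(a$filter_reason)) NA_character_
        else a$filter_reason),
        class = "annotated_variant")
    })
    tr <- if (length(o$trace)) do.call(rbind, lapply(o$trace, function(e)
      data.frame(stage = e$stage, record = e$record, reason = e$reason,
                 at = e$at %||% NA_integer_, stringsAsFactors = FALSE)))
    else empty_trace()
    mc <- unlist(o$match_counts)
    cs <- structure(list(
      case_id = o$case_id, owner = o$owner,
      variants = variants, profile = as.character(unlist(o$profile)),
      mode_of_inheritance = o$mode_of_inheritance %||% NA_character_,
      age_of_onset = o$age_of_onset %||% NA_character_,
      assembly_submitted = o$assembly_submitted %||% NA_character_,
      status = o$status, trace = tr,
      submitted_seq = as.integer(o$submitted_seq),
      match_counts = if (is.null(mc))
        stats::setNames(integer(), character())
      else stats::setNames(as.integer(mc), names(mc))),
      class = "case_record")
    wl$cases[[cs$case_id]] <- cs
    wl$seq <- max(wl$seq, cs$submitted_seq)
  }
  invisible(wl)
}

#' @export
print.case_record <- function(x, ...) {
  cat("Case", x$case_id, "(", x$owner, ") -", x$status, ":",
      length(x$variants), "variant(s),",
      length(x$profile), "phenotype term(s)\n")
  invisible(x)
}
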