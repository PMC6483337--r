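# Variant ingestion and normalization: VCF and genomic-HGVS parsing,
# left normalization to minimal representation, assembly conversion.

#' Construct a variant table
#'
#' Variants are plain data frames with one row per allele and columns
#' `assembly`, `chrom`, `pos` (1-based position of the first reference
#' base), `ref` and `alt` (non-empty uppercase allele strings).
#'
#' @param assembly Assembly label.
#' @param chrom Chromosome name(s); "chr" prefixes are stripped.
#' @param pos 1-based integer position(s).
#' @param ref,alt Allele strings (uppercased on ingest).
#' @return Data frame of variants.
#' @export
variant <- function(assembly, chrom, pos, ref, alt) {
  data.frame(assembly = assembly, chrom = canon_chrom(chrom),
             pos = as.integer(pos), ref = toupper(ref), alt = toupper(alt),
             stringsAsFactors = FALSE)
}

empty_variants <- function() {
  variant(character(), character(), integer(), character(), character())
}

variant_key <- function(v) {
  paste(v$assembly, v$chrom, v$pos, v$ref, v$alt, sep = ":")
}

variant_label <- function(v) {
  paste0(v$chrom, ":", v$pos, ":", v$ref, ">", v$alt)
}

.valid_allele <- function(x) grepl("^[ACGTN]+$", x)

#' Read site records from a VCF file
#'
#' Parses the CHROM/POS/REF/ALT site fields of a VCF 4.x stream.
#' Multi-allelic rows are split into one variant per ALT allele.
#' Symbolic alleles (`<DEL>`, breakends, `*`, `.`) and malformed rows
#' are rejected per row with a reason, never failing the whole file.
#' Genotype and sample columns are ignored.
#'
#' @param x Path to a VCF file or a character vector of VCF lines.
#' @param assembly Assembly label to attach to every variant.
#' @return List with `variants` (variant data frame) and `rejected`
#'   (data frame with columns `record`, `reason`).
#' @export
read_vcf <- function(x, assembly) {
  lines <- if (length(x) == 1L && !grepl("\n", x) && file.exists(x))
    readLines(x, warn = FALSE) else x
  lines <- lines[!startsWith(lines, "#") & nzchar(lines)]
  vars <- list()
  rej <- list()
  reject <- function(line, reason)
    rej[[length(rej) + 1L]] <<- data.frame(record = line, reason = reason,
                                           stringsAsFactors = FALSE)
  for (line in lines) {
    f <- strsplit(line, "\t", fixed = TRUE)[[1]]
    if (length(f) < 5L) { reject(line, "fewer than 5 columns"); next }
    pos <- suppressWarnings(as.integer(f[2]))
    if (is.na(pos) || pos < 1L) { reject(line, "invalid POS"); next }
    ref <- toupper(f[4])
    if (!.valid_allele(ref)) { reject(line, "invalid REF allele"); next }
    for (alt in strsplit(toupper(f[5]), ",", fixed = TRUE)[[1]]) {
      if (grepl("[<>*]", alt) || grepl("[", alt, fixed = TRUE) ||
          grepl("]", alt, fixed = TRUE) || alt == ".") {
        reject(line, "symbolic allele")
      } else if (!.valid_allele(alt)) {
        reject(line, "invalid ALT allele")
      } else if (alt == ref) {
        reject(line, "REF and ALT identical")
      } else {
        vars[[length(vars) + 1L]] <- variant(assembly, f[1], pos, ref, alt)
      }
    }
  }
  list(variants = if (length(vars)) do.call(rbind, vars) else empty_variants(),
       rejected = if (length(rej)) do.call(rbind, rej) else
         data.frame(record = character(), reason = character(),
                    stringsAsFactors = FALSE))
}

#' Parse a genomic (g.) HGVS expression
#'
#' Supports substitutions (`g.3G>T`), deletions (`g.4_5del`, `g.4del`,
#' optionally with the deleted sequence), duplications (`g.4_5dup`),
#' insertions (`g.3_4insTT`) and deletion-insertions
#' (`g.4_6delinsTT`), all with explicit genomic coordinates. Deletions,
#' duplications and insertions are anchored on a reference base so that
#' both alleles are non-empty (VCF style). Coding-, protein- or
#' RNA-level descriptions (c./p./r./n./m.) are not resolved locally and
#' raise an unsupported-level error.
#'
#' @param expr HGVS string, e.g. `"chrT:g.3G>T"`.
#' @param genome A `ref_genome` supplying anchor and deleted bases.
#' @param contig_map Optional named character vector mapping sequence
#'   accessions (e.g. RefSeq NC_ accessions) to chromosome names.
#' @return One-row variant data frame (not yet normalized).
#' @export
parse_hgvs_g <- function(expr, genome, contig_map = NULL) {
  expr <- trimws(expr)
  m <- regmatches(expr, regexec("^([^:]+):([a-z])\\.(.+)$", expr))[[1]]
  if (length(m) != 4L) stop("malformed HGVS expression: ", expr)
  acc <- m[2]; level <- m[3]; desc <- m[4]
  if (level != "g")
    stop("unsupported HGVS level '", level,
         ".' (only genomic g. descriptions are resolved locally): ", expr)
  chrom <- canon_chrom(acc)
  if (!is.null(contig_map) && acc %in% names(contig_map))
    chrom <- canon_chrom(contig_map[[acc]])
  if (!chrom %in% names(genome$sequences))
    stop("unknown sequence accession '", acc, "' in: ", expr)

  sub_m <- regmatches(desc, regexec("^(\\d+)([ACGTN])>([ACGTN])$", desc))[[1]]
  if (length(sub_m) == 4L) {
    pos <- as.integer(sub_m[2])
    return(variant(genome$assembly, chrom, pos, sub_m[3], sub_m[4]))
  }
  rng_m <- regmatches(
    desc, regexec("^(\\d+)(?:_(\\d+))?(del|dup|ins|delins)([ACGTN]*)$", desc)
  )[[1]]
  if (length(rng_m) != 5L) stop("unsupported HGVS description: ", expr)
  s <- as.integer(rng_m[2])
  e <- if (nzchar(rng_m[3])) as.integer(rng_m[3]) else s
  op <- rng_m[4]; seq <- rng_m[5]
  if (e < s) stop("inverted coordinate range in: ", expr)
  if (op == "ins") {
    if (e != s + 1L) stop("insertion coordinates must be adjacent: ", expr)
    if (!nzchar(seq)) stop("insertion without inserted sequence: ", expr)
    anchor <- ref_seq(genome, chrom, s, s)
    return(variant(genome$assembly, chrom, s, anchor, paste0(anchor, seq)))
  }
  if (op == "del") {
    deleted <- ref_seq(genome, chrom, s, e)
    if (nzchar(seq) && seq != deleted)
      stop("declared deleted sequence '", seq, "' does not match reference '",
           deleted, "' in: ", expr)
    if (s > 1L) {
      anchor <- ref_seq(genome, chrom, s - 1L, s - 1L)
      return(variant(genome$assembly, chrom, s - 1L,
                     paste0(anchor, deleted), anchor))
    }
    anchor <- ref_seq(genome, chrom, e + 1L, e + 1L)
    return(variant(genome$assembly, chrom, s, paste0(deleted, anchor), anchor))
  }
  if (op == "dup") {
    dupseq <- ref_seq(genome, chrom, s, e)
    anchor <- ref_seq(genome, chrom, e, e)
    return(variant(genome$assembly, chrom, e,
                   anchor, paste0(anchor, dupseq)))
  }
  # delins
  if (!nzchar(seq)) stop("delins without inserted sequence: ", expr)
  variant(genome$assembly, chrom, s, ref_seq(genome, chrom, s, e), seq)
}

#' Left-normalize variants to minimal representation
#'
#' Rewrites each variant to its left-most, minimal-length equivalent
#' against the reference: identical terminal bases of REF and ALT are
#' truncated; if an allele empties, the reference base to the left is
#' prepended to both and the position decremented; finally identical
#' leading bases are trimmed while both alleles keep length >= 2. The
#' result is idempotent, applies to the reference to give the same
#' mutated sequence as the input, and carries a left anchor base for
#' indels so no allele is ever empty.
#'
#' @param variants Variant data frame.
#' @param genome A `ref_genome`; REF alleles must match it at `pos`.
#' @return Variant data frame of the same row count and order.
#' @export
left_normalize <- function(variants, genome) {
  if (!nrow(variants)) return(variants)
  for (i in seq_len(nrow(variants))) {
    v <- variants[i, ]
    obs <- ref_seq(genome, v$chrom, v$pos, v$pos + nchar(v$ref) - 1L)
    if (obs != v$ref)
      stop("reference mismatch at ", v$chrom, ":", v$pos,
           " (expected '", v$ref, "', reference has '", obs, "')")
    res <- .normalize1(v$chrom, v$pos, v$ref, v$alt, genome)
    variants$pos[i] <- res$pos
    variants$ref[i] <- res$ref
    variants$alt[i] <- res$alt
  }
  variants
}

.normalize1 <- function(chrom, pos, ref, alt, genome) {
  repeat {
    while (nchar(ref) > 0L && nchar(alt) > 0L &&
           substr(ref, nchar(ref), nchar(ref)) ==
           substr(alt, nchar(alt), nchar(alt))) {
      ref <- substr(ref, 1L, nchar(ref) - 1L)
      alt <- substr(alt, 1L, nchar(alt) - 1L)
    }
    if (nchar(ref) > 0L && nchar(alt) > 0L) break
    if (pos <= 1L)
      stop("normalization walked off the 5' end of ", chrom)
    b <- ref_seq(genome, chrom, pos - 1L, pos - 1L)
    ref <- paste0(b, ref)
    alt <- paste0(b, alt)
    pos <- pos - 1L
  }
  while (nchar(ref) >= 2L && nchar(alt) >= 2L &&
         substr(ref, 1L, 1L) == substr(alt, 1L, 1L)) {
    ref <- substr(ref, 2L, nchar(ref))
    alt <- substr(alt, 2L, nchar(alt))
    pos <- pos + 1L
  }
  list(pos = pos, ref = ref, alt = alt)
}

#' Apply a variant to its reference sequence
#'
#' Utility (and test oracle) returning the full mutated chromosome
#' sequence that results from substituting ALT for REF at `pos`.
#'
#' @param v One-row variant data frame.
#' @param genome A `ref_genome`.
#' @return Mutated sequence string.
#' @export
apply_variant <- function(v, genome) {
  s <- genome$sequences[[canon_chrom(v$chrom)]]
  if (is.null(s)) stop("unknown chromosome: ", v$chrom)
  end <- v$pos + nchar(v$ref) - 1L
  if (substr(s, v$pos, end) != v$ref)
    stop("reference mismatch applying variant at ", v$chrom, ":", v$pos)
  paste0(substr(s, 1L, v$pos - 1L), v$alt,
         substr(s, end + 1L, nchar(s)))
}

#' Coordinate-mapping providers for assembly conversion
#'
#' `assembly_mapping` wraps an arbitrary position-mapping function;
#' `offset_mapping_from_file` loads a 4-column whitespace-separated
#' table (`chrom start end offset`) mapping every position inside
#' `[start, end]` to `pos + offset` — sufficient for fixtures and
#' simple liftovers. Positions outside every interval are unmappable.
#'
#' @param from,to Source and target assembly labels.
#' @param map Function `(chrom, pos) -> integer position or NA`.
#' @param path Path to the interval-offset table.
#' @return Object of class `assembly_mapping`.
#' @export
assembly_mapping <- function(from, to, map) {
  structure(list(from = from, to = to, map = map),
            class = "assembly_mapping")
}

#' @rdname assembly_mapping
#' @export
offset_mapping_from_file <- function(path, from, to) {
  tab <- utils::read.table(path, header = FALSE, stringsAsFactors = FALSE,
                           col.names = c("chrom", "start", "end", "offset"))
  tab$chrom <- canon_chrom(tab$chrom)
  assembly_mapping(from, to, function(chrom, pos) {
    hit <- which(tab$chrom == canon_chrom(chrom) &
                 tab$start <= pos & pos <= tab$end)
    if (!length(hit)) return(NA_integer_)
    as.integer(pos + tab$offset[hit[1]])
  })
}

#' Convert variant coordinates between assemblies
#'
#' Identity when the variant already carries the target assembly label.
#' Otherwise the position is remapped through the provider and the REF
#' allele re-verified against the target genome; failures (no covering
#' interval, reference disagreement) raise errors which the submission
#' pipeline records in the processing trace.
#'
#' @param variants Variant data frame.
#' @param target_genome `ref_genome` of the target assembly.
#' @param mappings List of `assembly_mapping` providers.
#' @return Variant data frame on the target assembly.
#' @export
convert_assembly <- function(variants, target_genome, mappings = list()) {
  if (!nrow(variants)) return(variants)
  target <- target_genome$assembly
  for (i in seq_len(nrow(variants))) {
    v <- variants[i, ]
    if (v$assembly == target) next
    prov <- NULL
    for (mp in mappings)
      if (mp$from == v$assembly && mp$to == target) { prov <- mp; break }
    if (is.null(prov))
      stop("no coordinate mapping available for ", v$assembly, " -> ", target)
    newpos <- prov$map(v$chrom, v$pos)
    if (is.na(newpos))
      stop("unmappable: ", variant_label(v), " has no interval in the ",
           v$assembly, " -> ", target, " mapping")
    obs <- ref_seq(target_genome, v$chrom, newpos,
                   newpos + nchar(v$ref) - 1L)
    if (obs != v$ref)
      stop("reference mismatch after conversion at ", v$chrom, ":", newpos,
           " (expected '", v$ref, "', target has '", obs, "')")
    variants$pos[i] <- newpos
    variants$assembly[i] <- target
  }
  variants
}

#' Write variants as a minimal site-only VCF
#'
#' @param variants Variant data frame.
#' @param path Output file.
#' @param chr_prefix Prepend "chr" to chromosome names on export.
#' @export
write_vcf <- function(variants, path, chr_prefix = FALSE) {
  hdr <- c("##fileformat=VCFv4.2",
           "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO")
  chrom <- if (chr_prefix) paste0("chr", variants$chrom) else variants$chrom
  rows <- if (nrow(variants))
    paste(chrom, variants$pos, ".", variants$ref, variants$alt,
          ".", ".", ".", sep = "\t") else character()
  writeLines(c(hdr, rows), path)
  invisible(path)
}

#' Validate a raw case submission
#'
#' Performs the submission sanity check: the assembly must be declared
#' and accepted, at least one variant must be extractable from the
#' declared sources (generic records, VCF, genomic HGVS strings), and
#' at least one phenotype term must resolve against the ontology
#' (alt_ids mapped, obsolete terms followed through `replaced_by`).
#' Individual failing variants or terms are recorded with reasons and
#' do not fail the submission; a submission with zero valid variants,
#' no resolvable phenotype term, or no acceptable assembly is rejected
#' as a whole.
#'
#' @param raw Submission list with fields `owner`, `assembly`,
#'   optional `variants` (list of generic records with chrom/pos/ref/alt),
#'   optional `vcf` (path or VCF lines), optional `hgvs` (character
#'   vector), and `hpo_terms`.
#' @param ont An `ontology`.
#' @param genome `ref_genome` used to resolve HGVS anchors (its
#'   assembly label need not match the submission's; coordinates are
#'   converted later).
#' @param accepted_assemblies Labels accepted at submission.
#' @return Object of class `validation_result`: list with `ok`,
#'   `accepted` (variant data frame), `rejected` (record/reason data
#'   frame), `profile_ok`, `terms` (resolved accessions), `reasons`.
#' @export
validate_submission <- function(raw, ont, genome,
                                accepted_assemblies = c("GRCh37", "GRCh38")) {
  reasons <- character()
  asm <- raw$assembly
  asm_ok <- !is.null(asm) && length(asm) == 1L && nzchar(asm) &&
    asm %in% accepted_assemblies
  if (is.null(asm) || !nzchar(asm %||% ""))
    reasons <- c(reasons, "missing assembly")
  else if (!asm_ok)
    reasons <- c(reasons, paste0("unaccepted assembly '", asm, "'"))

  accepted <- empty_variants()
  rejected <- data.frame(record = character(), reason = character(),
                         stringsAsFactors = FALSE)
  add_rej <- function(record, reason)
    rejected <<- rbind(rejected, data.frame(record = record, reason = reason,
                                            stringsAsFactors = FALSE))
  if (asm_ok) {
    for (rec in raw$variants %||% list()) {
      lbl <- paste(rec$chrom %||% "?", rec$pos %||% "?",
                   rec$ref %||% "?", rec$alt %||% "?", sep = ":")
      pos <- suppressWarnings(as.integer(rec$pos %||% NA))
      if (is.null(rec$chrom) || is.na(pos) || pos < 1L) {
        add_rej(lbl, "generic record lacks a valid chrom/pos")
      } else if (!.valid_allele(toupper(rec$ref %||% "")) ||
                 !.valid_allele(toupper(rec$alt %||% ""))) {
        add_rej(lbl, "generic record has invalid alleles")
      } else if (toupper(rec$ref) == toupper(rec$alt)) {
        add_rej(lbl, "REF and ALT identical")
      } else {
        accepted <- rbind(accepted,
                          variant(asm, rec$chrom, pos, rec$ref, rec$alt))
      }
    }
    if (!is.null(raw$vcf)) {
      r <- read_vcf(raw$vcf, asm)
      accepted <- rbind(accepted, r$variants)
      rejected <- rbind(rejected, r$rejected)
    }
    for (h in raw$hgvs %||% character()) {
      v <- tryCatch(parse_hgvs_g(h, genome), error = function(e) e)
      if (inherits(v, "error")) add_rej(h, conditionMessage(v))
      else { v$assembly <- asm; accepted <- rbind(accepted, v) }
    }
    if (!nrow(accepted) && !nrow(rejected))
      reasons <- c(reasons, "no variants in submission")
    else if (!nrow(accepted))
      reasons <- c(reasons, "no valid variants in submission")
  }

  terms <- character()
  for (id in unique(raw$hpo_terms %||% character())) {
    r <- resolve_term(ont, id)
    if (is.na(r)) add_rej(id, "unknown or obsolete phenotype term")
    else terms <- c(terms, r)
  }
  terms <- unique(terms)
  profile_ok <- length(terms) >= 1L
  if (!profile_ok) reasons <- c(reasons, "missing phenotype")

  structure(list(ok = asm_ok && nrow(accepted) >= 1L && profile_ok,
                 accepted = accepted, rejected = rejected,
                 profile_ok = profile_ok, terms = terms, reasons = reasons),
            class = "validation_result")
}
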