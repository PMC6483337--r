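# Local variant annotation: gene models from GFF3, codon-level
# consequence calling against the reference, impact classes, filters.
# A deliberately minimal deterministic annotator covering exactly what
# proximity matching needs: gene, codon ordinal, impact class.

CONSEQUENCE_IMPACT <- c(
  stop_gained = "HIGH", stop_lost = "HIGH", start_lost = "HIGH",
  frameshift = "HIGH",
  missense = "MODERATE", inframe_indel = "MODERATE",
  coding_sequence_variant = "MODERATE",
  synonymous = "LOW",
  utr_variant = "MODIFIER", intron_variant = "MODIFIER",
  upstream_gene_variant = "MODIFIER", downstream_gene_variant = "MODIFIER",
  intergenic_variant = "MODIFIER")

.complement <- function(x) chartr("ACGTN", "TGCAN", x)

empty_transcript_hits <- function() {
  data.frame(transcript_id = character(), gene_id = character(),
             region = character(), codon_index = integer(),
             consequence = character(), impact = character(),
             biotype = character(), canonical = logical(),
             pass = logical(), stringsAsFactors = FALSE)
}

#' Read gene models from a GFF3 file
#'
#' Assembles a hierarchical gene -> transcript -> exon/CDS model from
#' gene, mRNA/transcript, exon and CDS features linked by `Parent`
#' attributes. The canonical transcript per gene is taken from a
#' `canonical=1` attribute when present; otherwise the transcript with
#' the longest total CDS is flagged canonical (ties broken by id).
#'
#' @param path GFF3 file.
#' @return Object of class `gene_models`: list with `genes` (named list
#'   of gene records) and `transcripts` (named list with `gene_id`,
#'   `chrom`, `strand`, `biotype`, `canonical`, `exons` and `cds`
#'   interval data frames, `span`).
#' @export
read_gff3 <- function(path) {
  gr <- rtracklayer::import(path, format = "gff3")
  md <- S4Vectors::mcols(gr)
  df <- data.frame(
    seqnames = canon_chrom(as.character(GenomicRanges::seqnames(gr))),
    start = BiocGenerics::start(gr),
    end = BiocGenerics::end(gr),
    strand = as.character(BiocGenerics::strand(gr)),
    type = as.character(md$type),
    stringsAsFactors = FALSE)
  getcol <- function(nm) if (nm %in% colnames(md))
    as.character(md[[nm]]) else rep(NA_character_, nrow(df))
  ids <- getcol("ID")
  plist <- as.list(md$Parent)
  parents <- vapply(seq_len(nrow(df)), function(i) {
    p <- plist[[i]]
    if (length(p)) as.character(p)[1] else NA_character_
  }, character(1))
  df$phase <- if ("phase" %in% colnames(md)) md$phase else
    rep(NA_integer_, nrow(df))
  biotype <- getcol("biotype")
  bt2 <- getcol("gene_biotype")
  biotype[is.na(biotype)] <- bt2[is.na(biotype)]
  canonical_attr <- getcol("canonical")
  nm <- getcol("Name")

  genes <- list()
  for (i in which(df$type == "gene")) {
    genes[[ids[i]]] <- list(
      id = ids[i], name = if (!is.na(nm[i])) nm[i] else ids[i],
      chrom = df$seqnames[i], strand = df$strand[i],
      biotype = biotype[i] %||% NA_character_,
      start = df$start[i], end = df$end[i])
  }
  txs <- list()
  for (i in which(df$type %in% c("mRNA", "transcript"))) {
    txs[[ids[i]]] <- list(
      id = ids[i], gene_id = parents[i], chrom = df$seqnames[i],
      strand = df$strand[i],
      biotype = if (!is.na(biotype[i])) biotype[i] else "protein_coding",
      canonical = identical(canonical_attr[i], "1") ||
        identical(tolower(canonical_attr[i] %||% ""), "true"),
      exons = data.frame(start = integer(), end = integer()),
      cds = data.frame(start = integer(), end = integer(),
                       phase = integer()))
  }
  for (i in which(df$type == "exon")) {
    p <- parents[i]
    if (is.na(p) || is.null(txs[[p]]))
      stop("exon without parent transcript at line for ",
           df$seqnames[i], ":", df$start[i])
    txs[[p]]$exons <- rbind(txs[[p]]$exons,
                            data.frame(start = df$start[i], end = df$end[i]))
  }
  for (i in which(df$type == "CDS")) {
    p <- parents[i]
    if (is.na(p) || is.null(txs[[p]]))
      stop("CDS feature without parent transcript at ",
           df$seqnames[i], ":", df$start[i], "-", df$end[i])
    ph <- suppressWarnings(as.integer(as.character(df$phase[i])))
    txs[[p]]$cds <- rbind(txs[[p]]$cds,
                          data.frame(start = df$start[i], end = df$end[i],
                                     phase = ph %||% NA_integer_))
  }
  for (id in names(txs)) {
    txs[[id]]$exons <- txs[[id]]$exons[order(txs[[id]]$exons$start), ,
                                       drop = FALSE]
    txs[[id]]$cds <- txs[[id]]$cds[order(txs[[id]]$cds$start), , drop = FALSE]
    txs[[id]]$span <- if (nrow(txs[[id]]$exons))
      c(min(txs[[id]]$exons$start), max(txs[[id]]$exons$end))
    else c(NA_integer_, NA_integer_)
    cl <- sum(txs[[id]]$cds$end - txs[[id]]$cds$start + 1L)
    if (nrow(txs[[id]]$cds) && cl %% 3L != 0L)
      message("note: CDS length of ", id, " is not a multiple of 3")
  }
  # canonical default: longest CDS per gene
  for (g in names(genes)) {
    gt <- names(Filter(function(t) identical(t$gene_id, g), txs))
    if (!length(gt) || any(vapply(gt, function(t) txs[[t]]$canonical,
                                  logical(1)))) next
    cl <- vapply(gt, function(t)
      sum(txs[[t]]$cds$end - txs[[t]]$cds$start + 1L), numeric(1))
    best <- gt[order(-cl, gt)][1]
    txs[[best]]$canonical <- TRUE
  }
  structure(list(genes = genes, transcripts = txs), class = "gene_models")
}

#' @export
print.gene_models <- function(x, ...) {
  cat("Gene models:", length(x$genes), "genes,",
      length(x$transcripts), "transcripts\n")
  invisible(x)
}

#' Genomic CDS positions of a transcript in coding (5'->3') order
#'
#' @param tx A transcript record from a `gene_models` object.
#' @return Integer vector of genomic positions; element `k` is the
#'   k-th coding base in transcript orientation.
#' @export
cds_positions <- function(tx) {
  if (!nrow(tx$cds)) return(integer())
  pos <- unlist(lapply(seq_len(nrow(tx$cds)), function(i)
    seq.int(tx$cds$start[i], tx$cds$end[i])))
  if (tx$strand == "-") rev(pos) else pos
}

#' Codon ordinal of a genomic position within a transcript
#'
#' For positions inside the CDS, the 1-based codon ordinal counting
#' coding bases 5' to 3' in transcript orientation (position k of the
#' CDS lies in codon `(k - 1) %/% 3 + 1`); `NA` for non-CDS positions.
#'
#' @param tx Transcript record.
#' @param genomic_pos 1-based genomic position.
#' @return Integer codon ordinal or `NA_integer_`.
#' @export
codon_index <- function(tx, genomic_pos) {
  k <- match(genomic_pos, cds_positions(tx))
  if (is.na(k)) return(NA_integer_)
  as.integer((k - 1L) %/% 3L + 1L)
}

.codon_seq <- function(tx, genome, codon_idx) {
  cp <- cds_positions(tx)
  idx <- (codon_idx - 1L) * 3L + 1:3
  if (any(idx > length(cp))) return(NULL)
  gp <- cp[idx]
  bases <- vapply(gp, function(p)
    ref_seq(genome, tx$chrom, p, p), character(1))
  if (tx$strand == "-") bases <- .complement(bases)
  list(codon = paste(bases, collapse = ""), positions = gp)
}

.translate_codon <- function(codon) {
  aa <- Biostrings::GENETIC_CODE[[codon]]
  if (is.null(aa)) NA_character_ else aa
}

#' Annotate a variant against local gene models
#'
#' Classifies the variant's region per overlapping transcript (CDS,
#' UTR, intron, or up-/downstream within `flank` bp), resolves the
#' affected codon, and calls a consequence: CDS substitutions are
#' translated before and after with the standard genetic code
#' (synonymous, missense, stop_gained, stop_lost, start_lost); CDS
#' length changes are frameshift when the length difference is not a
#' multiple of 3, else inframe_indel; non-coding regions map to
#' MODIFIER consequences. Impact classes: HIGH (stop_gained, stop_lost,
#' start_lost, frameshift), MODERATE (missense, inframe_indel), LOW
#' (synonymous), MODIFIER (all non-coding). A variant outside every
#' gene is annotated intergenic with no transcript hits.
#'
#' @param v One-row variant data frame (normalized, on the annotation
#'   assembly).
#' @param models A `gene_models` object.
#' @param genome A `ref_genome`.
#' @param maf_table Optional named numeric vector of allele frequencies
#'   keyed `chrom:pos:ref:alt` (see [read_maf_vcf()]).
#' @param flank Up-/downstream window in bp.
#' @return Object of class `annotated_variant`: list with `variant`
#'   (the input row), `gene_ids`, `transcript_hits` (data frame),
#'   `maf`, `passed_filters` (NA until filtered), `beacon_hit`.
#' @export
annotate_variant <- function(v, models, genome, maf_table = NULL,
                             flank = 1000L) {
  span <- c(v$pos, v$pos + nchar(v$ref) - 1L)
  hits <- list()
  for (tx in models$transcripts) {
    if (tx$chrom != v$chrom || is.na(tx$span[1])) next
    dist_ok <- span[1] <= tx$span[2] + flank && span[2] >= tx$span[1] - flank
    if (!dist_ok) next
    inside <- span[1] <= tx$span[2] && span[2] >= tx$span[1]
    cp <- cds_positions(tx)
    vpos <- seq.int(span[1], span[2])
    region <- if (inside) {
      if (any(vpos %in% cp)) "CDS"
      else if (any(vapply(seq_len(nrow(tx$exons)), function(i)
        span[1] <= tx$exons$end[i] && span[2] >= tx$exons$start[i],
        logical(1)))) "UTR"
      else "intron"
    } else {
      before <- span[2] < tx$span[1]
      if ((before && tx$strand == "+") || (!before && tx$strand == "-"))
        "upstream" else "downstream"
    }
    res <- .classify_hit(v, tx, genome, region, cp, vpos)
    hits[[length(hits) + 1L]] <- data.frame(
      transcript_id = tx$id, gene_id = tx$gene_id, region = region,
      codon_index = res$codon_index, consequence = res$consequence,
      impact = unname(CONSEQUENCE_IMPACT[res$consequence]),
      biotype = tx$biotype, canonical = tx$canonical, pass = NA,
      stringsAsFactors = FALSE)
  }
  th <- if (length(hits)) do.call(rbind, hits) else empty_transcript_hits()
  maf <- if (!is.null(maf_table))
    unname(maf_table[paste(v$chrom, v$pos, v$ref, v$alt, sep = ":")])
  else NA_real_
  if (length(maf) == 0L) maf <- NA_real_
  structure(list(variant = v,
                 gene_ids = unique(th$gene_id),
                 transcript_hits = th,
                 maf = maf,
                 passed_filters = NA,
                 beacon_hit = FALSE),
            class = "annotated_variant")
}

.classify_hit <- function(v, tx, genome, region, cp, vpos) {
  if (region != "CDS") {
    cons <- switch(region, UTR = "utr_variant", intron = "intron_variant",
                   upstream = "upstream_gene_variant",
                   downstream = "downstream_gene_variant")
    return(list(consequence = cons, codon_index = NA_integer_))
  }
  delta <- nchar(v$ref) - nchar(v$alt)
  coding_vpos <- vpos[vpos %in% cp]
  codons <- unique(vapply(coding_vpos, function(p) codon_index(tx, p),
                          integer(1)))
  one_codon <- length(codons) == 1L
  if (nchar(v$ref) == 1L && nchar(v$alt) == 1L) {
    ci <- codons[1]
    cs <- .codon_seq(tx, genome, ci)
    if (is.null(cs))
      return(list(consequence = "coding_sequence_variant", codon_index = ci))
    k <- match(v$pos, cs$positions)
    base <- if (tx$strand == "-") .complement(v$alt) else v$alt
    mut <- cs$codon
    substr(mut, k, k) <- base
    aa_ref <- .translate_codon(cs$codon)
    aa_alt <- .translate_codon(mut)
    cons <- if (is.na(aa_ref) || is.na(aa_alt)) "coding_sequence_variant"
    else if (ci == 1L && aa_ref == "M" && aa_alt != "M") "start_lost"
    else if (aa_ref != "*" && aa_alt == "*") "stop_gained"
    else if (aa_ref == "*" && aa_alt != "*") "stop_lost"
    else if (aa_ref == aa_alt) "synonymous"
    else "missense"
    return(list(consequence = cons, codon_index = ci))
  }
  if (delta %% 3L != 0L)
    return(list(consequence = "frameshift",
                codon_index = if (one_codon) codons[1] else NA_integer_))
  list(consequence = "inframe_indel",
       codon_index = if (one_codon) codons[1] else NA_integer_)
}

#' Filter configuration for matchability
#'
#' Variants lacking a sufficiently deleterious predicted effect, or
#' failing the frequency / biotype / canonical gates, are excluded from
#' matching. An absent minor allele frequency passes the MAF gate
#' (absence of evidence does not exclude).
#'
#' @param max_maf Maximum minor allele frequency.
#' @param min_impact Least severe impact class still considered
#'   deleterious (one of HIGH, MODERATE, LOW, MODIFIER).
#' @param require_protein_coding Keep only protein_coding transcripts.
#' @param canonical_only Keep only canonical transcripts.
#' @return Object of class `filter_config`.
#' @export
filter_config <- function(max_maf = 0.01, min_impact = "MODERATE",
                          require_protein_coding = FALSE,
                          canonical_only = FALSE) {
  stopifnot(min_impact %in% IMPACT_LEVELS, max_maf >= 0, max_maf <= 1)
  structure(list(max_maf = max_maf, min_impact = min_impact,
                 require_protein_coding = require_protein_coding,
                 canonical_only = canonical_only),
            class = "filter_config")
}

#' Apply matchability filters to an annotated variant
#'
#' Sets `passed_filters` and per-hit `pass` flags: a variant passes iff
#' its MAF is absent or at most `max_maf` and at least one transcript
#' hit survives the impact / biotype / canonical gates. Failing hits
#' are dropped from matching consideration (flagged, not deleted).
#'
#' @param av An `annotated_variant`.
#' @param cfg A `filter_config`.
#' @return The `annotated_variant` with `passed_filters`, per-hit
#'   `pass` flags and, when excluded, a `filter_reason`.
#' @export
apply_filters <- function(av, cfg = filter_config()) {
  th <- av$transcript_hits
  maf_ok <- is.na(av$maf) || av$maf <= cfg$max_maf
  pass <- rep(FALSE, nrow(th))
  if (nrow(th)) {
    pass <- impact_rank(th$impact) <= impact_rank(cfg$min_impact)
    if (cfg$require_protein_coding)
      pass <- pass & th$biotype == "protein_coding"
    if (cfg$canonical_only)
      pass <- pass & th$canonical
  }
  av$transcript_hits$pass <- pass & maf_ok
  av$passed_filters <- maf_ok && any(pass)
  av$filter_reason <- if (av$passed_filters) NA_character_
  else if (!maf_ok) "MAF above threshold"
  else if (!nrow(th) || all(th$impact == "MODIFIER"))
    "no deleterious effect predicted"
  else "no transcript hit passes the configured filters"
  av
}

#' @export
print.annotated_variant <- function(x, ...) {
  cat(variant_label(x$variant), "-", nrow(x$transcript_hits),
      "transcript hit(s);",
      if (isTRUE(x$passed_filters)) "matchable" else "not matchable", "\n")
  invisible(x)
}

#' Read a local allele-frequency table from VCF
#'
#' Uses the `AF` INFO field (one value per ALT allele) of a site-only
#' VCF as the minor-allele-frequency source for the MAF filter.
#'
#' @param x Path to a VCF file or VCF lines.
#' @return Named numeric vector keyed `chrom:pos:ref:alt`.
#' @export
read_maf_vcf <- function(x) {
  lines <- if (length(x) == 1L && !grepl("\n", x) && file.exists(x))
    readLines(x, warn = FALSE) else x
  lines <- lines[!startsWith(lines, "#") & nzchar(lines)]
  out <- numeric()
  for (line in lines) {
    f <- strsplit(line, "\t", fixed = TRUE)[[1]]
    if (length(f) < 8L) next
    afm <- regmatches(f[8], regexec("(?:^|;)AF=([^;]+)", f[8]))[[1]]
    if (length(afm) != 2L) next
    afs <- suppressWarnings(as.numeric(strsplit(afm[2], ",")[[1]]))
    alts <- strsplit(toupper(f[5]), ",", fixed = TRUE)[[1]]
    for (k in seq_along(alts)) {
      if (k > length(afs) || is.na(afs[k])) next
      key <- paste(canon_chrom(f[1]), f[2], toupper(f[4]), alts[k], sep = ":")
      out[key] <- afs[k]
    }
  }
  out
}
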