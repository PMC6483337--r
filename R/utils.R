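`%||%` <- function(a, b) if (is.null(a)) b else a

#' @keywords internal
new_trace_entry <- function(stage, record, reason, at = NA_integer_) {
  data.frame(stage = stage, record = record, reason = reason, at = at,
             stringsAsFactors = FALSE)
}

empty_trace <- function() {
  data.frame(stage = character(), record = character(),
             reason = character(), at = integer(), stringsAsFactors = FALSE)
}

# Impact classes in decreasing severity; rank 1 is most severe.
IMPACT_LEVELS <- c("HIGH", "MODERATE", "LOW", "MODIFIER")

impact_rank <- function(impact) match(impact, IMPACT_LEVELS)

# Canonical chromosome naming: "chr" prefixes stripped on ingest so the
# three input formats (VCF, GFF3, HGVS) agree internally.
canon_chrom <- function(x) sub("^chr", "", x)
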