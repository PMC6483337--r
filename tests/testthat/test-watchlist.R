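test_that("submission pipeline processes, traces and matches end to end", {
  eng <- toy_engine(seed = 41, n_genes = 4L)
  wl <- eng$wl
  # first case into an empty list: processed, zero matches
  s1 <- simple_submission(eng, gene_idx = 1L, owner = "alice")
  r1 <- submit_case(wl, s1)
  expect_equal(r1$case$status, "PROCESSED")
  expect_equal(nrow(r1$reports[[1]]$matches), 0L)

  # identical variant from another user: IDENTICAL match both ways
  s2 <- simple_submission(eng, gene_idx = 1L, owner = "bob")
  r2 <- submit_case(wl, s2)
  m <- r2$reports[[1]]$matches
  expect_equal(nrow(m), 1L)
  expect_equal(m$category, "IDENTICAL")
  expect_length(r2$reports, 2L)
  expect_equal(r2$reports[[2]]$recipient, "alice")
  expect_equal(r2$reports[[2]]$matches$query_case_id, r1$case$case_id)
  # identical profiles -> phenotype similarity 1
  expect_equal(m$similarity, 1)

  # growth: both submissions became PROCESSED cases
  expect_length(wl$cases, 2L)
})

test_that("failed validation and unmatchable variants are traced, not
           thrown", {
  eng <- toy_engine(seed = 43, n_genes = 4L)
  wl <- eng$wl
  # no phenotype: whole submission FAILED with trace
  s <- simple_submission(eng, gene_idx = 1L)
  s$hpo_terms <- NULL
  r <- submit_case(wl, s)
  expect_equal(r$case$status, "FAILED")
  expect_true(any(grepl("missing phenotype", r$case$trace$reason)))
  expect_length(r$reports, 0L)

  # a variant failing the impact filter: PROCESSED, traced, 0 matchable
  tx <- eng$models$transcripts[[1]]
  cp <- cds_positions(tx)
  gc <- Biostrings::GENETIC_CODE
  syn <- NULL
  for (ci in 3:12) {
    cs <- casematch:::.codon_seq(tx, eng$genome, ci)
    for (k in 1:3) {
      p <- cs$positions[k]
      gref <- ref_seq(eng$genome, tx$chrom, p, p)
      for (b in setdiff(c("A", "C", "G", "T"), gref)) {
        cb <- if (tx$strand == "-") chartr("ACGT", "TGCA", b) else b
        mutc <- cs$codon; substr(mutc, k, k) <- cb
        if (gc[[mutc]] == gc[[cs$codon]]) syn <- list(p = p, ref = gref,
                                                      alt = b)
      }
    }
    if (!is.null(syn)) break
  }
  s2 <- simple_submission(eng, gene_idx = 1L, owner = "u2")
  s2$variants <- list(list(chrom = tx$chrom, pos = syn$p, ref = syn$ref,
                           alt = syn$alt))
  r2 <- submit_case(wl, s2)
  expect_equal(r2$case$status, "PROCESSED")
  expect_true(any(grepl("excluded from matching", r2$case$trace$reason)))
  expect_true(any(grepl("no matchable variants", r2$case$trace$reason)))
  expect_false(r2$case$variants[[1]]$passed_filters)

  # partition property: every input variant is stored or traced
  s3 <- simple_submission(eng, gene_idx = 2L, owner = "u3")
  s3$variants <- c(s3$variants,
                   list(list(chrom = tx$chrom, pos = 10, ref = "Z",
                             alt = "T")))
  r3 <- submit_case(wl, s3)
  expect_equal(r3$case$status, "PROCESSED")
  n_stored <- length(r3$case$variants)
  n_traced <- sum(r3$case$trace$stage %in%
                    c("validate", "normalize", "convert", "extract"))
  expect_equal(n_stored + n_traced, 2L)
})

test_that("beacon hits flag and trace but never remove from matching", {
  eng0 <- toy_engine(seed = 45, n_genes = 4L)
  s1 <- simple_submission(eng0, gene_idx = 1L, owner = "alice")
  v <- s1$variants[[1]]
  # known store carries the SAME allele in a non-minimal representation
  pre <- ref_seq(eng0$genome, v$chrom, v$pos - 1L, v$pos - 1L)
  known_vcf <- c("#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO",
                 paste(v$chrom, v$pos - 1L, ".", paste0(pre, v$ref),
                       paste0(pre, v$alt), ".", ".", ".", sep = "\t"))
  known <- load_known_variants(known_vcf, eng0$genome)
  eng <- toy_engine(seed = 45, n_genes = 4L, known = known)
  r1 <- submit_case(eng$wl, s1)
  expect_true(r1$case$variants[[1]]$beacon_hit)
  expect_true(any(grepl("already publicized", r1$case$trace$reason)))
  expect_true(r1$case$variants[[1]]$passed_filters)
  # still matchable by a later identical submission
  s2 <- simple_submission(eng, gene_idx = 1L, owner = "bob")
  r2 <- submit_case(eng$wl, s2)
  expect_equal(r2$reports[[1]]$matches$category, "IDENTICAL")
  # absent variant: no hit
  expect_false(beacon_check(variant(eng$genome$assembly, "T1", 5,
                                    ref_seq(eng$genome, "T1", 5, 5), "N"),
                            known))
})

test_that("retraction removes cases from future matching only", {
  eng <- toy_engine(seed = 47, n_genes = 4L)
  wl <- eng$wl
  r1 <- submit_case(wl, simple_submission(eng, gene_idx = 1L,
                                          owner = "alice"))
  retract_case(wl, r1$case$case_id)
  expect_equal(wl$cases[[r1$case$case_id]]$status, "RETRACTED")
  # identical resubmission finds nothing
  r2 <- submit_case(wl, simple_submission(eng, gene_idx = 1L,
                                          owner = "bob"))
  expect_equal(nrow(r2$reports[[1]]$matches), 0L)
  # unknown id and double retraction
  expect_error(retract_case(wl, "CASE-999999"), "unknown case")
  expect_error(retract_case(wl, r1$case$case_id), "already retracted")
  expect_silent(retract_case(wl, r1$case$case_id, on_double = "noop"))
})

test_that("case status reports flags, match counts and the trace", {
  eng <- toy_engine(seed = 49, n_genes = 4L)
  wl <- eng$wl
  r1 <- submit_case(wl, simple_submission(eng, gene_idx = 1L,
                                          owner = "alice"))
  st1 <- case_status(wl, r1$case$case_id)
  expect_equal(st1$status, "PROCESSED")
  expect_equal(st1$variants$match_count, 0L)
  # an identical second case raises both parties' counts
  r2 <- submit_case(wl, simple_submission(eng, gene_idx = 1L,
                                          owner = "bob"))
  expect_gte(case_status(wl, r2$case$case_id)$variants$match_count, 1L)
  expect_gte(case_status(wl, r1$case$case_id)$variants$match_count, 1L)
  # FAILED case keeps a non-empty trace
  bad <- simple_submission(eng, gene_idx = 2L)
  bad$assembly <- NULL
  rb <- submit_case(wl, bad)
  stb <- case_status(wl, rb$case$case_id)
  expect_equal(stb$status, "FAILED")
  expect_gt(nrow(stb$trace), 0L)
  expect_error(case_status(wl, "CASE-999999"), "unknown case")
})

test_that("store export/import round-trips and replay is byte-identical", {
  build <- function() {
    eng <- toy_engine(seed = 51, n_genes = 6L)
    subs <- list(
      simple_submission(eng, gene_idx = 1L, owner = "a"),
      simple_submission(eng, gene_idx = 1L, owner = "b"),
      simple_submission(eng, gene_idx = 2L, owner = "c", codon = 4L),
      simple_submission(eng, gene_idx = 2L, owner = "d", codon = 7L))
    reports <- list()
    for (s in subs) reports[[length(reports) + 1L]] <-
      submit_case(eng$wl, s)$reports
    list(eng = eng, reports = reports)
  }
  one <- build()
  two <- build()
  f1 <- tempfile(); f2 <- tempfile()
  v1 <- tempfile(fileext = ".vcf"); v2 <- tempfile(fileext = ".vcf")
  export_store(one$eng$wl, f1, v1)
  export_store(two$eng$wl, f2, v2)
  expect_identical(readLines(f1), readLines(f2))
  expect_identical(readLines(v1), readLines(v2))
  # rendered reports identical across replays
  r1 <- unlist(lapply(one$reports, function(rs)
    lapply(rs, format_report_tsv)))
  r2 <- unlist(lapply(two$reports, function(rs)
    lapply(rs, format_report_tsv)))
  expect_identical(r1, r2)

  # import into a fresh watch list: same matching behaviour
  eng3 <- toy_engine(seed = 51, n_genes = 6L)
  import_store(eng3$wl, f1)
  expect_length(eng3$wl$cases, 4L)
  r <- submit_case(eng3$wl, simple_submission(eng3, gene_idx = 1L,
                                              owner = "e"))
  expect_equal(r$reports[[1]]$matches$category[1], "IDENTICAL")
  # re-export of the imported store matches the original cases
  f3 <- tempfile()
  eng4 <- toy_engine(seed = 51, n_genes = 6L)
  import_store(eng4$wl, f1)
  export_store(eng4$wl, f3)
  expect_identical(readLines(f3), readLines(f1))
})

test_that("rescan rebuilds matches and counters from scratch", {
  eng <- toy_engine(seed = 53, n_genes = 4L)
  wl <- eng$wl
  r1 <- submit_case(wl, simple_submission(eng, gene_idx = 1L, owner = "a"))
  r2 <- submit_case(wl, simple_submission(eng, gene_idx = 1L, owner = "b"))
  before1 <- case_status(wl, r1$case$case_id)$variants$match_count
  reports <- rescan(wl)
  expect_equal(case_status(wl, r1$case$case_id)$variants$match_count,
               before1)
  expect_equal(reports[[r2$case$case_id]][[1]]$matches$category,
               "IDENTICAL")
})
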