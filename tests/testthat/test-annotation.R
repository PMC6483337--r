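test_that("GFF3 gene models parse with exons, CDS and canonical flags", {
  fx <- fixture_gene_models()
  m <- fx$models
  expect_length(m$genes, 2L)
  expect_length(m$transcripts, 2L)
  tf <- m$transcripts[["TF"]]
  expect_equal(sum(tf$cds$end - tf$cds$start + 1L), 60L)
  expect_equal(tf$strand, "+")
  expect_equal(m$transcripts[["TR"]]$strand, "-")
  # single transcript per gene gets the canonical default
  expect_true(tf$canonical)

  # two transcripts, no canonical attribute: longer CDS wins
  gff <- c("##gff-version 3",
    "c1\tt\tgene\t1\t100\t.\t+\t.\tID=G1",
    "c1\tt\tmRNA\t1\t100\t.\t+\t.\tID=T1;Parent=G1",
    "c1\tt\texon\t1\t100\t.\t+\t.\tID=T1.e;Parent=T1",
    "c1\tt\tCDS\t10\t39\t.\t+\t0\tID=T1.c;Parent=T1",
    "c1\tt\tmRNA\t1\t100\t.\t+\t.\tID=T2;Parent=G1",
    "c1\tt\texon\t1\t100\t.\t+\t.\tID=T2.e;Parent=T2",
    "c1\tt\tCDS\t10\t69\t.\t+\t0\tID=T2.c;Parent=T2")
  f <- tempfile(fileext = ".gff3"); writeLines(gff, f)
  m2 <- read_gff3(f)
  expect_false(m2$transcripts[["T1"]]$canonical)
  expect_true(m2$transcripts[["T2"]]$canonical)

  # CDS without a parent transcript is a format error
  bad <- c("##gff-version 3",
           "c1\tt\tCDS\t10\t39\t.\t+\t0\tID=x.c;Parent=NOPE")
  fb <- tempfile(fileext = ".gff3"); writeLines(bad, fb)
  expect_error(read_gff3(fb), "CDS.*without parent transcript")
})

test_that("codon ordinals follow the coding-offset convention on both
           strands", {
  fx <- fixture_gene_models()
  tf <- fx$models$transcripts[["TF"]]
  # forward CDS starting at 101
  expect_equal(vapply(101:104, function(p) codon_index(tf, p), integer(1)),
               c(1L, 1L, 1L, 2L))
  tr <- fx$models$transcripts[["TR"]]
  # reverse CDS ending at 260: rightmost base is codon 1
  expect_equal(codon_index(tr, 260L), 1L)
  expect_equal(codon_index(tr, 257L), 2L)
  # intronic / outside positions have no codon
  expect_true(is.na(codon_index(tf, 95L)))
  # agreement with the splice-and-index oracle at every CDS position
  for (tx in fx$models$transcripts) {
    for (p in cds_positions(tx))
      expect_identical(codon_index(tx, p),
                       oracle_codon_index(tx, fx$genome, p))
  }
})

test_that("codon oracle agreement holds for generated multi-exon genes", {
  gen <- generate_toy_genome(n_genes = 4L, chrom_length = 6000L, seed = 11)
  genome <- read_genome_fasta(gen$fasta, gen$assembly)
  models <- read_gff3(gen$gff3)
  for (tx in models$transcripts) {
    cp <- cds_positions(tx)
    probe <- cp[unique(c(1L, length(cp), sample(seq_along(cp), 15L)))]
    for (p in probe)
      expect_identical(codon_index(tx, p),
                       oracle_codon_index(tx, genome, p))
  }
})

test_that("consequences are called from before/after codon translation", {
  fx <- fixture_gene_models()
  g <- fx$genome
  m <- fx$models
  tf <- m$transcripts[["TF"]]
  cp <- cds_positions(tf)

  # find a codon whose 3rd-base change creates a stop (translate oracle)
  gc <- Biostrings::GENETIC_CODE
  found <- NULL
  for (ci in 2:19) {
    cod <- substr(fx$fwd_cds, (ci - 1) * 3 + 1, ci * 3)
    for (b in c("A", "C", "G", "T")) {
      for (k in 1:3) {
        mutc <- cod; substr(mutc, k, k) <- b
        if (mutc != cod && gc[[mutc]] == "*" && gc[[cod]] != "*") {
          found <- list(ci = ci, k = k, alt = b, cod = cod)
          break
        }
      }
      if (!is.null(found)) break
    }
    if (!is.null(found)) break
  }
  expect_false(is.null(found))
  pos <- cp[(found$ci - 1) * 3 + found$k]
  v <- variant("toy", "chrF", pos, substr(found$cod, found$k, found$k),
               found$alt)
  av <- annotate_variant(v, m, g)
  hit <- av$transcript_hits[av$transcript_hits$transcript_id == "TF", ]
  expect_equal(hit$consequence, "stop_gained")
  expect_equal(hit$impact, "HIGH")
  expect_equal(hit$codon_index, found$ci)

  # synonymous: change a codon's wobble base to a synonym
  syn <- NULL
  for (ci in 2:19) {
    cod <- substr(fx$fwd_cds, (ci - 1) * 3 + 1, ci * 3)
    for (b in setdiff(c("A", "C", "G", "T"), substr(cod, 3, 3))) {
      mutc <- cod; substr(mutc, 3, 3) <- b
      if (gc[[mutc]] == gc[[cod]]) { syn <- list(ci = ci, alt = b,
                                                 cod = cod); break }
    }
    if (!is.null(syn)) break
  }
  pos_s <- cp[(syn$ci - 1) * 3 + 3]
  vs <- variant("toy", "chrF", pos_s, substr(syn$cod, 3, 3), syn$alt)
  avs <- annotate_variant(vs, m, g)
  hs <- avs$transcript_hits[avs$transcript_hits$transcript_id == "TF", ]
  expect_equal(hs$consequence, "synonymous")
  expect_equal(hs$impact, "LOW")

  # 2 bp CDS deletion is a frameshift (2 mod 3 != 0)
  p2 <- cp[7]
  vdel <- variant("toy", "chrF", p2 - 1L,
                  ref_seq(g, "chrF", p2 - 1L, p2 + 1L),
                  ref_seq(g, "chrF", p2 - 1L, p2 - 1L))
  avd <- annotate_variant(vdel, m, g)
  hd <- avd$transcript_hits[avd$transcript_hits$transcript_id == "TF", ]
  expect_equal(hd$consequence, "frameshift")
  expect_equal(hd$impact, "HIGH")

  # losing the ATG is start_lost
  vstart <- variant("toy", "chrF", cp[1], "A", "C")
  hstart <- annotate_variant(vstart, m, g)$transcript_hits
  hstart <- hstart[hstart$transcript_id == "TF", ]
  expect_equal(hstart$consequence, "start_lost")

  # far from every gene: intergenic, no transcript hits
  vout <- annotate_variant(variant("toy", "chrF", 390,
                                   ref_seq(g, "chrF", 390, 390),
                                   if (ref_seq(g, "chrF", 390, 390) == "A")
                                     "C" else "A"), m, g, flank = 10L)
  expect_equal(nrow(vout$transcript_hits), 0L)
  expect_length(vout$gene_ids, 0L)
})

test_that("reverse-strand consequences match forward calls on the
           mirrored genome", {
  fx <- fixture_gene_models()
  g <- fx$genome
  m <- fx$models
  tr <- m$transcripts[["TR"]]
  cp <- cds_positions(tr)
  gc <- Biostrings::GENETIC_CODE
  # mutate codon 5, base 2 of the minus-strand ORF and predict by hand
  ci <- 5L; k <- 2L
  cod <- substr(fx$rev_cds, (ci - 1) * 3 + 1, ci * 3)
  alt_coding <- setdiff(c("A", "C", "G", "T"), substr(cod, k, k))[1]
  mutc <- cod; substr(mutc, k, k) <- alt_coding
  expected <- if (gc[[mutc]] == gc[[cod]]) "synonymous"
  else if (gc[[mutc]] == "*") "stop_gained" else "missense"
  gpos <- cp[(ci - 1) * 3 + k]
  gref <- ref_seq(g, "chrF", gpos, gpos)
  galt <- chartr("ACGT", "TGCA", alt_coding)
  av <- annotate_variant(variant("toy", "chrF", gpos, gref, galt), m, g)
  h <- av$transcript_hits[av$transcript_hits$transcript_id == "TR", ]
  expect_equal(h$consequence, expected)
  expect_equal(h$codon_index, ci)
})

test_that("filters gate on impact, MAF, biotype and canonical status", {
  fx <- fixture_gene_models()
  g <- fx$genome; m <- fx$models
  tf <- m$transcripts[["TF"]]
  cp <- cds_positions(tf)
  gc <- Biostrings::GENETIC_CODE
  # a missense variant (MODERATE)
  mis <- NULL
  for (ci in 2:19) {
    cod <- substr(fx$fwd_cds, (ci - 1) * 3 + 1, ci * 3)
    for (b in setdiff(c("A", "C", "G", "T"), substr(cod, 1, 1))) {
      mutc <- cod; substr(mutc, 1, 1) <- b
      if (gc[[mutc]] != gc[[cod]] && gc[[mutc]] != "*") {
        mis <- list(pos = cp[(ci - 1) * 3 + 1],
                    ref = substr(cod, 1, 1), alt = b)
        break
      }
    }
    if (!is.null(mis)) break
  }
  v <- variant("toy", "chrF", mis$pos, mis$ref, mis$alt)

  av <- apply_filters(annotate_variant(v, m, g), filter_config())
  expect_true(av$passed_filters)

  # HIGH-only threshold excludes the missense variant
  av2 <- apply_filters(annotate_variant(v, m, g),
                       filter_config(min_impact = "HIGH"))
  expect_false(av2$passed_filters)

  # synonymous-only variants fail the default MODERATE threshold
  syn_pos <- NULL
  for (ci in 2:19) {
    cod <- substr(fx$fwd_cds, (ci - 1) * 3 + 1, ci * 3)
    for (b in setdiff(c("A", "C", "G", "T"), substr(cod, 3, 3))) {
      mutc <- cod; substr(mutc, 3, 3) <- b
      if (gc[[mutc]] == gc[[cod]]) {
        syn_pos <- list(pos = cp[(ci - 1) * 3 + 3],
                        ref = substr(cod, 3, 3), alt = b)
        break
      }
    }
    if (!is.null(syn_pos)) break
  }
  vsyn <- variant("toy", "chrF", syn_pos$pos, syn_pos$ref, syn_pos$alt)
  avs <- apply_filters(annotate_variant(vsyn, m, g), filter_config())
  expect_false(avs$passed_filters)
  expect_match(avs$filter_reason, "no deleterious|no transcript hit")

  # MAF gate: present and above threshold excludes
  maf <- stats::setNames(0.05, paste("F", mis$pos, mis$ref, mis$alt,
                                     sep = ":"))
  avm <- apply_filters(annotate_variant(v, m, g, maf_table = maf),
                       filter_config(max_maf = 0.01))
  expect_false(avm$passed_filters)
  expect_equal(avm$filter_reason, "MAF above threshold")
  # absent MAF passes the gate
  expect_true(apply_filters(annotate_variant(v, m, g),
                            filter_config(max_maf = 0))$passed_filters)
})

test_that("relaxing filters never shrinks the matchable set", {
  gen <- generate_toy_genome(n_genes = 4L, chrom_length = 6000L, seed = 5)
  genome <- read_genome_fasta(gen$fasta, gen$assembly)
  models <- read_gff3(gen$gff3)
  set.seed(9)
  avs <- list()
  for (rep in 1:30) {
    chrom <- names(genome$sequences)[1]
    pos <- sample.int(nchar(genome$sequences[[1]]) - 2L, 1L)
    ref <- ref_seq(genome, chrom, pos, pos)
    alt <- sample(setdiff(c("A", "C", "G", "T"), ref), 1L)
    avs[[rep]] <- annotate_variant(variant(gen$assembly, chrom, pos,
                                           ref, alt), models, genome)
  }
  passed <- function(cfg) which(vapply(avs, function(a)
    apply_filters(a, cfg)$passed_filters, logical(1)))
  strict <- passed(filter_config(min_impact = "HIGH", max_maf = 0.001))
  mid <- passed(filter_config(min_impact = "MODERATE", max_maf = 0.01))
  loose <- passed(filter_config(min_impact = "MODIFIER", max_maf = 1))
  expect_true(all(strict %in% mid))
  expect_true(all(mid %in% loose))
})

test_that("AF INFO fields populate the frequency table", {
  vcf <- c("##fileformat=VCFv4.2",
           "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO",
           "chr1\t100\t.\tA\tT\t.\t.\tAF=0.12;DP=10",
           "chr1\t200\t.\tG\tC,A\t.\t.\tAF=0.01,0.002",
           "chr1\t300\t.\tG\tC\t.\t.\tDP=5")
  tab <- read_maf_vcf(vcf)
  expect_equal(unname(tab["1:100:A:T"]), 0.12)
  expect_equal(unname(tab["1:200:G:A"]), 0.002)
  expect_false("1:300:G:C" %in% names(tab))
})
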