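# Synthetic-fixture generators: mini ontologies, toy genomes with gene
# models, and case cohorts with planted match structure. Everything the
# engine consumes can be generated offline, deterministically per seed,
# and is read back only through the package's public parsers. Fixtures
# are structural, not biological: they exercise formats and matching
# semantics, not realistic allele-frequency spectra or disease biology.

.with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  force(expr)
}

.rand_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n,
                                      replace = TRUE), collapse = "")

STOP_CODONS <- c("TAA", "TAG", "TGA")

#' Generate a mini ontology in OBO format
#'
#' Builds a rooted hierarchy of `depth + 1` levels with `branching`
#' children per term (so a tree has `sum(branching^(0:depth))` terms),
#' then turns the requested fraction of terms at levels >= 2 into
#' multi-parent terms by adding a second `is_a` edge to another term
#' one level up. Identical seed and parameters yield identical files.
#'
#' @param depth Number of levels below the root (>= 2).
#' @param branching Children per term (>= 1).
#' @param multi_parent_fraction Fraction of eligible terms receiving a
#'   second parent; requires `depth >= 3` and `branching >= 2`.
#' @param seed Integer seed.
#' @param path Optional file to write the OBO text to.
#' @param prefix Accession prefix for generated terms.
#' @return List with `obo` (character lines), `terms` (data frame:
#'   `id`, `depth`, `parent`), `root_id`, and `path` when written.
#' @export
generate_mini_ontology <- function(depth = 4L, branching = 2L,
                                   multi_parent_fraction = 0,
                                   seed = 1L, path = NULL,
                                   prefix = "TT") {
  stopifnot(depth >= 2L, branching >= 1L)
  if (multi_parent_fraction > 0 && (depth < 3L || branching < 2L))
    stop("multi_parent_fraction > 0 requires depth >= 3 and branching >= 2")
  .with_seed(seed, {
    ids <- character(); depths <- integer(); parent1 <- character()
    parents <- list()
    counter <- 0L
    mk_id <- function() {
      counter <<- counter + 1L
      sprintf("%s:%07d", prefix, counter)
    }
    root <- mk_id()
    ids <- root; depths <- 0L; parent1 <- NA_character_
    parents[[root]] <- character()
    prev <- root
    for (lv in seq_len(depth)) {
      cur <- character()
      for (p in prev) for (k in seq_len(branching)) {
        id <- mk_id()
        ids <- c(ids, id); depths <- c(depths, lv); parent1 <- c(parent1, p)
        parents[[id]] <- p
        cur <- c(cur, id)
      }
      prev <- cur
    }
    if (multi_parent_fraction > 0) {
      eligible <- ids[depths >= 2L]
      n_multi <- round(multi_parent_fraction * length(eligible))
      if (n_multi > 0L) {
        chosen <- sort(sample(eligible, n_multi))
        for (id in chosen) {
          lv <- depths[match(id, ids)]
          cands <- setdiff(ids[depths == lv - 1L], parents[[id]])
          if (length(cands))
            parents[[id]] <- c(parents[[id]], sample(cands, 1L))
        }
      }
    }
    obo <- c("format-version: 1.2",
             paste0("data-version: mini/", seed), "")
    for (i in seq_along(ids)) {
      id <- ids[i]
      obo <- c(obo, "[Term]", paste0("id: ", id),
               paste0("name: synthetic term ", i),
               paste0("is_a: ", parents[[id]]), "")
    }
    if (!is.null(path)) writeLines(obo, path)
    list(obo = obo,
         terms = data.frame(id = ids, depth = depths, parent = parent1,
                            stringsAsFactors = FALSE),
         root_id = root, path = path)
  })
}

#' Generate a toy genome with gene models
#'
#' Writes a FASTA reference and matching GFF3 gene models: genes with
#' 1-3 exons, an ATG-initiated CDS of length divisible by 3 without
#' internal stop codons, a terminal stop codon, strands per
#' `strand_mix`, short UTRs, and a CA-repeat tract on the first
#' chromosome for normalization tests. Genes are laid out in
#' non-overlapping slots.
#'
#' @param n_genes Number of genes (>= 1).
#' @param chrom_length Chromosome length in bp
#'   (>= 200 * genes per chromosome).
#' @param n_chroms Number of chromosomes; genes are distributed round
#'   robin.
#' @param strand_mix `"both"`, `"forward"` or `"reverse"`.
#' @param seed Integer seed.
#' @param dir Directory for `genome.fa` and `genes.gff3` (created).
#' @param assembly Assembly label for the fixture.
#' @return List with `fasta`, `gff3` (paths), `assembly`, and `genes`
#'   (data frame: `gene_id`, `tx_id`, `chrom`, `strand`, `n_codons`).
#' @export
generate_toy_genome <- function(n_genes = 4L, chrom_length = 6000L,
                                n_chroms = 1L,
                                strand_mix = c("both", "forward", "reverse"),
                                seed = 1L, dir = tempfile("toygenome"),
                                assembly = "toy1") {
  strand_mix <- match.arg(strand_mix)
  genes_per_chrom <- ceiling(n_genes / n_chroms)
  stopifnot(chrom_length >= 200L * genes_per_chrom)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  .with_seed(seed, {
    seqs <- stats::setNames(
      vapply(seq_len(n_chroms), function(i) .rand_dna(chrom_length),
             character(1)),
      paste0("chrT", seq_len(n_chroms)))
    # tandem repeat tract for left-normalization tests
    substr(seqs[1], 101, 120) <- strrep("CA", 10L)

    gff <- c("##gff-version 3")
    ginfo <- list()
    margin <- 160L
    slot <- (chrom_length - margin) %/% genes_per_chrom
    for (g in seq_len(n_genes)) {
      chrom_i <- ((g - 1L) %% n_chroms) + 1L
      chrom <- names(seqs)[chrom_i]
      slot_i <- (g - 1L) %/% n_chroms
      region_start <- margin + slot_i * slot + 1L
      strand <- switch(strand_mix, forward = "+", reverse = "-",
                       both = if (g %% 2L == 1L) "+" else "-")
      n_codons <- sample(18:30, 1L)  # internal codons
      coding <- paste0("ATG",
                       paste(sample(setdiff(names(Biostrings::GENETIC_CODE),
                                            STOP_CODONS),
                                    n_codons, replace = TRUE),
                             collapse = ""),
                       "TAA")
      cds_len <- nchar(coding)
      n_exons <- sample(1:3, 1L)
      # split CDS (in coding order) into n_exons chunks of >= 6 bp
      if (n_exons > 1L) {
        cuts <- sort(sample(seq(6L, cds_len - 6L, by = 3L) +
                              sample(0:2, 1L), n_exons - 1L))
        cuts <- unique(pmin(pmax(cuts, 2L), cds_len - 2L))
        n_exons <- length(cuts) + 1L
        chunk_len <- diff(c(0L, cuts, cds_len))
      } else chunk_len <- cds_len
      intron_len <- if (n_exons > 1L) sample(30:60, n_exons - 1L,
                                             replace = TRUE) else integer()
      utr5 <- 10L; utr3 <- 10L
      genomic_cds <- if (strand == "+") coding else
        .complement(paste(rev(strsplit(coding, "")[[1]]), collapse = ""))
      genomic_chunks <- if (strand == "+") chunk_len else rev(chunk_len)

      # lay the gene out left to right on the genome
      pos <- region_start + 20L
      gene_start <- pos
      exon_iv <- matrix(integer(), ncol = 2)
      cds_iv <- matrix(integer(), ncol = 2)
      offset <- 0L
      for (e in seq_along(genomic_chunks)) {
        len <- genomic_chunks[e]
        ex_start <- pos
        lead <- if (e == 1L) (if (strand == "+") utr5 else utr3) else 0L
        cds_start <- pos + lead
        chunk_seq <- substr(genomic_cds, offset + 1L, offset + len)
        substr(seqs[chrom_i], cds_start, cds_start + len - 1L) <- chunk_seq
        offset <- offset + len
        trail <- if (e == length(genomic_chunks))
          (if (strand == "+") utr3 else utr5) else 0L
        ex_end <- cds_start + len - 1L + trail
        exon_iv <- rbind(exon_iv, c(ex_start, ex_end))
        cds_iv <- rbind(cds_iv, c(cds_start, cds_start + len - 1L))
        pos <- ex_end + if (e < length(genomic_chunks))
          intron_len[e] + 1L else 1L
      }
      gene_end <- max(exon_iv[, 2])
      gid <- sprintf("GENE%03d", g)
      tid <- sprintf("TX%03d", g)
      # GFF3 phase per CDS feature, in transcript (5'->3') order
      ord <- if (strand == "+") seq_len(nrow(cds_iv)) else
        rev(seq_len(nrow(cds_iv)))
      phases <- integer(nrow(cds_iv))
      done <- 0L
      for (k in ord) {
        phases[k] <- (3L - done %% 3L) %% 3L
        done <- done + cds_iv[k, 2] - cds_iv[k, 1] + 1L
      }
      gff <- c(gff,
        paste(chrom, "toyfix", "gene", gene_start, gene_end, ".", strand,
              ".", paste0("ID=", gid, ";Name=", gid,
                          ";biotype=protein_coding"), sep = "\t"),
        paste(chrom, "toyfix", "mRNA", gene_start, gene_end, ".", strand,
              ".", paste0("ID=", tid, ";Parent=", gid,
                          ";biotype=protein_coding"), sep = "\t"))
      for (k in seq_len(nrow(exon_iv)))
        gff <- c(gff, paste(chrom, "toyfix", "exon", exon_iv[k, 1],
                            exon_iv[k, 2], ".", strand, ".",
                            paste0("ID=", tid, ".e", k, ";Parent=", tid),
                            sep = "\t"))
      for (k in seq_len(nrow(cds_iv)))
        gff <- c(gff, paste(chrom, "toyfix", "CDS", cds_iv[k, 1],
                            cds_iv[k, 2], ".", strand, phases[k],
                            paste0("ID=", tid, ".c", k, ";Parent=", tid),
                            sep = "\t"))
      ginfo[[g]] <- data.frame(gene_id = gid, tx_id = tid, chrom = chrom,
                               strand = strand, n_codons = n_codons + 2L,
                               stringsAsFactors = FALSE)
    }
    fasta <- file.path(dir, "genome.fa")
    con <- file(fasta, "w")
    for (nm in names(seqs)) {
      writeLines(paste0(">", nm), con)
      writeLines(substring(seqs[[nm]], seq(1, nchar(seqs[[nm]]), 70),
                           pmin(seq(1, nchar(seqs[[nm]]), 70) + 69,
                                nchar(seqs[[nm]]))), con)
    }
    close(con)
    gff3 <- file.path(dir, "genes.gff3")
    writeLines(gff, gff3)
    list(fasta = fasta, gff3 = gff3, assembly = assembly,
         genes = do.call(rbind, ginfo))
  })
}

# All deleterious (missense / stop_gained) single-base substitutions in
# one codon of a transcript, as genomic variant candidates.
.deleterious_snvs <- function(tx, genome, codon_idx, assembly) {
  cs <- .codon_seq(tx, genome, codon_idx)
  if (is.null(cs)) return(empty_variants())
  out <- list()
  aa_ref <- .translate_codon(cs$codon)
  if (is.na(aa_ref) || aa_ref == "*") return(empty_variants())
  for (k in 1:3) {
    p <- cs$positions[k]
    gref <- ref_seq(genome, tx$chrom, p, p)
    for (b in setdiff(c("A", "C", "G", "T"), gref)) {
      cb <- if (tx$strand == "-") .complement(b) else b
      mut <- cs$codon
      substr(mut, k, k) <- cb
      aa_alt <- .translate_codon(mut)
      if (is.na(aa_alt) || aa_alt == aa_ref) next
      if (codon_idx == 1L) next  # keep clear of start-codon edge cases
      out[[length(out) + 1L]] <- variant(assembly, tx$chrom, p, gref, b)
    }
  }
  if (length(out)) do.call(rbind, out) else empty_variants()
}

.term_branches <- function(ont, terms_df) {
  # level-1 ancestor via first parents, for planting profile overlap
  anc <- function(id) {
    d <- terms_df$depth[match(id, terms_df$id)]
    while (d > 1L) {
      id <- terms_df$parent[match(id, terms_df$id)]
      d <- d - 1L
    }
    id
  }
  vapply(terms_df$id, anc, character(1))
}

#' Generate a case cohort with planted match structure
#'
#' Produces raw case submissions whose pairwise matches are known by
#' construction: for every planted pair, two cases carrying variants
#' that realize exactly the requested proximity category in a dedicated
#' gene (deleterious substitutions found by scanning the codon table,
#' guaranteeing filter passage), with phenotype profiles sharing terms
#' to the requested overlap (`"high"` = identical profiles, `"medium"`
#' = sibling terms, `"low"` = terms in different top-level branches).
#' Filler cases each occupy their own gene, so they match nothing.
#'
#' @param n_cases Total cases; must be at least `2 * length(planted_pairs)`.
#' @param planted_pairs List of `list(category=, phenotype_overlap=)`
#'   with category in IDENTICAL, SAME_POSITION, SAME_CODON, SAME_GENE
#'   and overlap in high, medium, low.
#' @param ont Parsed mini `ontology`.
#' @param genome `ref_genome` of the toy genome.
#' @param models `gene_models` of the toy genome.
#' @param seed Integer seed.
#' @return List with `submissions` (list of raw submission lists, in
#'   submission order) and `truth` (data frame: `case_a`, `case_b`
#'   submission indices, `category`, `overlap`, `gene_id`).
#' @export
generate_cohort <- function(n_cases, planted_pairs, ont, genome, models,
                            seed = 1L) {
  n_pairs <- length(planted_pairs)
  if (n_cases < 2L * n_pairs)
    stop("n_cases too small for ", n_pairs, " planted pairs")
  n_filler <- n_cases - 2L * n_pairs
  need_genes <- n_pairs + n_filler
  gene_ids <- sort(names(models$genes))
  if (length(gene_ids) < need_genes)
    stop("over-constrained plant: need ", need_genes, " genes, models have ",
         length(gene_ids))
  depths <- .term_depths(ont)
  terms_df <- data.frame(id = names(depths), depth = unname(depths),
                         parent = vapply(names(depths), function(id) {
                           p <- ont$terms[[id]]$parents
                           if (length(p)) p[1] else NA_character_
                         }, character(1)),
                         stringsAsFactors = FALSE)
  branches <- .term_branches(ont, terms_df)

  .with_seed(seed, {
    deep <- terms_df$id[terms_df$depth == max(terms_df$depth)]
    pick_profiles <- function(overlap) {
      if (overlap == "high") {
        t <- sample(deep, 1L)
        return(list(t, t))
      }
      if (overlap == "medium") {
        # two siblings sharing their parent, as deep as available
        cand <- terms_df[terms_df$depth >= 2L, ]
        par <- sample(unique(cand$parent[duplicated(cand$parent)]), 1L)
        sibs <- sample(cand$id[cand$parent == par], 2L)
        return(list(sibs[1], sibs[2]))
      }
      # low: deep terms from different top-level branches
      b <- unique(branches[terms_df$depth >= 2L])
      bs <- sample(b, 2L)
      t1 <- sample(terms_df$id[branches == bs[1] & terms_df$depth >= 2L], 1L)
      t2 <- sample(terms_df$id[branches == bs[2] & terms_df$depth >= 2L], 1L)
      list(t1, t2)
    }

    tx_of_gene <- function(g) {
      tids <- names(Filter(function(t) identical(t$gene_id, g),
                           models$transcripts))
      models$transcripts[[sort(tids)[1]]]
    }

    subs <- list()
    truth <- list()
    gene_pool <- gene_ids
    for (pi in seq_len(n_pairs)) {
      p <- planted_pairs[[pi]]
      g <- gene_pool[1]; gene_pool <- gene_pool[-1]
      tx <- tx_of_gene(g)
      nc <- length(cds_positions(tx)) %/% 3L
      ci <- sample(3:(nc - 2L), 1L)
      vs <- NULL
      if (p$category == "IDENTICAL") {
        cand <- .deleterious_snvs(tx, genome, ci, genome$assembly)
        vs <- list(cand[1, ], cand[1, ])
      } else if (p$category == "SAME_POSITION") {
        found <- FALSE
        for (try_ci in c(ci, setdiff(3:(nc - 2L), ci))) {
          cand <- .deleterious_snvs(tx, genome, try_ci, genome$assembly)
          tab <- table(cand$pos)
          pos2 <- as.integer(names(tab)[tab >= 2L])
          if (length(pos2)) {
            two <- cand[cand$pos == pos2[1], ][1:2, ]
            vs <- list(two[1, ], two[2, ]); found <- TRUE; break
          }
        }
        if (!found) stop("over-constrained plant: no SAME_POSITION site in ", g)
      } else if (p$category == "SAME_CODON") {
        cand <- .deleterious_snvs(tx, genome, ci, genome$assembly)
        ps <- unique(cand$pos)
        if (length(ps) < 2L) stop("over-constrained plant: codon ", ci,
                                  " of ", g, " lacks two mutable positions")
        vs <- list(cand[cand$pos == ps[1], ][1, ],
                   cand[cand$pos == ps[2], ][1, ])
      } else if (p$category == "SAME_GENE") {
        cand1 <- .deleterious_snvs(tx, genome, ci, genome$assembly)
        cand2 <- .deleterious_snvs(tx, genome, ci + 2L, genome$assembly)
        vs <- list(cand1[1, ], cand2[1, ])
      } else stop("unknown planted category: ", p$category)
      prof <- pick_profiles(p$phenotype_overlap %||% "high")
      ia <- length(subs) + 1L
      for (side in 1:2) {
        v <- vs[[side]]
        subs[[length(subs) + 1L]] <- list(
          owner = sprintf("user%03d", length(subs) + 1L),
          assembly = genome$assembly,
          variants = list(list(chrom = v$chrom, pos = v$pos,
                               ref = v$ref, alt = v$alt)),
          hpo_terms = as.list(prof[[side]]))
      }
      truth[[pi]] <- data.frame(case_a = ia, case_b = ia + 1L,
                                category = p$category,
                                overlap = p$phenotype_overlap %||% "high",
                                gene_id = g, stringsAsFactors = FALSE)
    }
    for (f in seq_len(n_filler)) {
      g <- gene_pool[1]; gene_pool <- gene_pool[-1]
      tx <- tx_of_gene(g)
      nc <- length(cds_positions(tx)) %/% 3L
      ci <- sample(3:(nc - 2L), 1L)
      cand <- .deleterious_snvs(tx, genome, ci, genome$assembly)
      v <- cand[1, ]
      t <- sample(terms_df$id[terms_df$depth >= 1L], 1L)
      subs[[length(subs) + 1L]] <- list(
        owner = sprintf("user%03d", length(subs) + 1L),
        assembly = genome$assembly,
        variants = list(list(chrom = v$chrom, pos = v$pos,
                             ref = v$ref, alt = v$alt)),
        hpo_terms = list(t))
    }
    list(submissions = subs,
         truth = if (length(truth)) do.call(rbind, truth) else
           data.frame(case_a = integer(), case_b = integer(),
                      category = character(), overlap = character(),
                      gene_id = character(), stringsAsFactors = FALSE))
  })
}

# shortest-path depth of every non-obsolete term (root = 0)
.term_depths <- function(ont) {
  active <- names(Filter(function(t) !t$obsolete, ont$terms))
  depths <- stats::setNames(rep(NA_integer_, length(active)), active)
  depths[ont$root_id] <- 0L
  frontier <- ont$root_id
  d <- 0L
  while (length(frontier)) {
    d <- d + 1L
    nxt <- character()
    for (id in active) {
      if (!is.na(depths[id])) next
      if (any(ont$terms[[id]]$parents %in% frontier)) {
        depths[id] <- d
        nxt <- c(nxt, id)
      }
    }
    frontier <- nxt
  }
  depths
}
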