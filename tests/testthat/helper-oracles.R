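# Shared fixtures and independent oracles. The oracles deliberately
# re-derive results by different means than the package (sequence-based
# enumeration, physical CDS splicing) so they can referee it.

# ---- tiny ontologies built in code ------------------------------------

obo_lines <- function(edges, root = "T:1", obsolete = character(),
                      extra = character()) {
  # edges: named list child -> character vector of parents
  ids <- unique(c(root, names(edges), unlist(edges)))
  out <- c("format-version: 1.2", "")
  for (id in ids) {
    out <- c(out, "[Term]", paste0("id: ", id), paste0("name: term ", id))
    for (p in edges[[id]] %||% character())
      out <- c(out, paste0("is_a: ", p, " ! parent"))
    if (id %in% obsolete) out <- c(out, "is_obsolete: true")
    out <- c(out, "")
  }
  c(out, extra)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# chain r -> a -> b plus sibling b2 under a
ont_chain_sibling <- function() {
  parse_obo(obo_lines(list(`T:2` = "T:1", `T:3` = "T:2", `T:4` = "T:2")))
}

# chain of length 5: r -> a -> b -> c -> d
ont_chain5 <- function() {
  parse_obo(obo_lines(list(`T:2` = "T:1", `T:3` = "T:2",
                           `T:4` = "T:3", `T:5` = "T:4")))
}

# diamond: c has parents a and b, both children of r
ont_diamond <- function() {
  parse_obo(obo_lines(list(`T:2` = "T:1", `T:3` = "T:1",
                           `T:4` = c("T:2", "T:3"))))
}

# random DAG ontology: node i's parents drawn from earlier nodes
random_dag_ontology <- function(n, extra_parent_p = 0.15) {
  ids <- sprintf("R:%d", seq_len(n))
  edges <- list()
  for (i in 2:n) {
    p1 <- ids[sample.int(i - 1L, 1L)]
    ps <- p1
    if (i > 2 && stats::runif(1) < extra_parent_p)
      ps <- unique(c(ps, ids[sample.int(i - 1L, 1L)]))
    edges[[ids[i]]] <- ps
  }
  parse_obo(obo_lines(edges, root = ids[1]))
}

# ---- independent root-path / similarity oracle ------------------------

# iterative stack-based enumeration of all parent-edge node SEQUENCES,
# reduced to distinct node sets
oracle_root_paths <- function(ont, term) {
  out <- list()
  stack <- list(term)
  while (length(stack)) {
    seqv <- stack[[length(stack)]]
    stack[[length(stack)]] <- NULL
    head <- seqv[length(seqv)]
    if (head == ont$root_id) {
      out[[length(out) + 1L]] <- sort(unique(seqv))
    } else {
      for (p in ont$terms[[head]]$parents)
        stack[[length(stack) + 1L]] <- c(seqv, p)
    }
  }
  keys <- vapply(out, paste, character(1), collapse = "|")
  out[!duplicated(keys)]
}

oracle_term_sim <- function(ont, c1, c2) {
  p1 <- oracle_root_paths(ont, c1)
  p2 <- oracle_root_paths(ont, c2)
  max(vapply(p1, function(p) max(vapply(p2, function(q)
    length(intersect(p, q)) / length(union(p, q)), numeric(1))),
    numeric(1)))
}

# ---- toy reference + variant oracles ----------------------------------

toy_ref <- function() ref_genome(c(chrT = "GGGCACACACG"), "toy")

# repeat-rich random reference for normalization property tests
random_repeat_ref <- function(len = 400) {
  units <- c("A", "C", "G", "T", "CA", "CAG", "AT", "GGC")
  s <- ""
  while (nchar(s) < len) {
    u <- sample(units, 1L)
    s <- paste0(s, strrep(u, sample.int(6L, 1L)))
  }
  ref_genome(c(chrR = substr(s, 1, len)), "toy")
}

random_variant <- function(genome, chrom = "chrR") {
  s <- genome$sequences[[canonical(chrom)]]
  n <- nchar(s)
  pos <- sample(30:(n - 30), 1L)
  reflen <- sample.int(4L, 1L)
  ref <- substr(s, pos, pos + reflen - 1L)
  altlen <- sample.int(4L, 1L)
  alt <- paste(sample(c("A", "C", "G", "T"), altlen, replace = TRUE),
               collapse = "")
  if (alt == ref) alt <- paste0(alt, "T")
  variant(genome$assembly, chrom, pos, ref, alt)
}

canonical <- function(x) sub("^chr", "", x)

# Enumerate every VCF-style representation (pos', ref', alt') within a
# +/- `window` bp window whose application to the reference yields the
# same mutated chromosome; used to certify left-most minimality.
equivalent_representations <- function(v, genome, window = 20L) {
  s <- genome$sequences[[canonical(v$chrom)]]
  mut <- apply_variant(v, genome)
  lo <- max(1L, v$pos - window)
  hi <- min(nchar(s), v$pos + window)
  maxlen <- nchar(v$ref) + nchar(v$alt) + window
  out <- list()
  for (p in lo:hi) {
    for (rl in 0:maxlen) {
      if (p + rl - 1L > nchar(s)) break
      ref <- substr(s, p, p + rl - 1L)
      al <- nchar(mut) - (nchar(s) - rl)
      if (al < 0L) next
      alt <- substr(mut, p, p + al - 1L)
      # does this triple reproduce the mutated sequence?
      cand <- paste0(substr(s, 1, p - 1L), alt,
                     substr(s, p + rl, nchar(s)))
      if (cand != mut) next
      if (!nzchar(ref) || !nzchar(alt) || ref == alt) next
      out[[length(out) + 1L]] <- data.frame(pos = p, ref = ref, alt = alt,
                                            stringsAsFactors = FALSE)
    }
  }
  unique(do.call(rbind, out))
}

is_minimal_rep <- function(ref, alt) {
  no_suffix <- substr(ref, nchar(ref), nchar(ref)) !=
    substr(alt, nchar(alt), nchar(alt))
  no_trimmable_prefix <- nchar(ref) < 2L || nchar(alt) < 2L ||
    substr(ref, 1, 1) != substr(alt, 1, 1)
  no_suffix && no_trimmable_prefix
}

# ---- gene-model fixture built in code ---------------------------------

# one forward gene (CDS 101-160) and one reverse gene (CDS 201-260) on a
# 400 bp chromosome; reverse CDS is the reverse complement of a clean ORF
fixture_gene_models <- function() {
  set.seed(42)
  bg <- paste(sample(c("A", "C", "G", "T"), 400, replace = TRUE),
              collapse = "")
  orf <- function(n) paste0(
    "ATG", paste(sample(setdiff(names(Biostrings::GENETIC_CODE),
                                c("TAA", "TAG", "TGA")), n, replace = TRUE),
                 collapse = ""), "TAA")
  fwd <- orf(18)                      # 60 bp
  rev_cds <- orf(18)
  revcomp <- function(x) chartr("ACGT", "TGCA",
                                paste(rev(strsplit(x, "")[[1]]),
                                      collapse = ""))
  s <- bg
  substr(s, 101, 160) <- fwd
  substr(s, 201, 260) <- revcomp(rev_cds)
  genome <- ref_genome(c(chrF = s), "toy")
  gff <- c("##gff-version 3",
    "chrF\ttest\tgene\t91\t170\t.\t+\t.\tID=GF;biotype=protein_coding",
    "chrF\ttest\tmRNA\t91\t170\t.\t+\t.\tID=TF;Parent=GF;biotype=protein_coding",
    "chrF\ttest\texon\t91\t170\t.\t+\t.\tID=TF.e1;Parent=TF",
    "chrF\ttest\tCDS\t101\t160\t.\t+\t0\tID=TF.c1;Parent=TF",
    "chrF\ttest\tgene\t191\t270\t.\t-\t.\tID=GR;biotype=protein_coding",
    "chrF\ttest\tmRNA\t191\t270\t.\t-\t.\tID=TR;Parent=GR;biotype=protein_coding",
    "chrF\ttest\texon\t191\t270\t.\t-\t.\tID=TR.e1;Parent=TR",
    "chrF\ttest\tCDS\t201\t260\t.\t-\t0\tID=TR.c1;Parent=TR")
  path <- tempfile(fileext = ".gff3")
  writeLines(gff, path)
  list(genome = genome, models = read_gff3(path), gff_path = path,
       fwd_cds = fwd, rev_cds = rev_cds)
}

# splice-and-translate codon oracle: physically extract the CDS,
# reverse-complement for minus strand, and index the base
oracle_codon_index <- function(tx, genome, genomic_pos) {
  pieces <- vapply(seq_len(nrow(tx$cds)), function(i)
    ref_seq(genome, tx$chrom, tx$cds$start[i], tx$cds$end[i]), character(1))
  gpos <- unlist(lapply(seq_len(nrow(tx$cds)), function(i)
    seq.int(tx$cds$start[i], tx$cds$end[i])))
  if (tx$strand == "-") gpos <- rev(gpos)
  k <- match(genomic_pos, gpos)
  if (is.na(k)) return(NA_integer_)
  as.integer((k - 1L) %/% 3L + 1L)
}

# ---- end-to-end fixture helpers ---------------------------------------

toy_engine <- function(seed = 1L, n_genes = 6L, chrom_length = 8000L,
                       depth = 4L, branching = 2L, mp = 0.2, ...) {
  onto <- generate_mini_ontology(depth = depth, branching = branching,
                                 multi_parent_fraction = mp, seed = seed)
  ont <- parse_obo(onto$obo)
  gen <- generate_toy_genome(n_genes = n_genes,
                             chrom_length = chrom_length, seed = seed)
  genome <- read_genome_fasta(gen$fasta, gen$assembly)
  models <- read_gff3(gen$gff3)
  list(ont = ont, genome = genome, models = models, gen = gen,
       onto = onto,
       wl = watchlist(ont, genome, models, ...))
}

simple_submission <- function(engine, gene_idx = 1L, terms = NULL,
                              owner = "userA", codon = 5L, alt_i = 1L) {
  models <- engine$models
  g <- sort(names(models$genes))[gene_idx]
  tid <- names(Filter(function(t) identical(t$gene_id, g),
                      models$transcripts))[1]
  tx <- models$transcripts[[tid]]
  cand <- casematch:::.deleterious_snvs(tx, engine$genome, codon,
                                        engine$genome$assembly)
  v <- cand[alt_i, ]
  if (is.null(terms)) {
    depths <- casematch:::.term_depths(engine$ont)
    terms <- names(depths)[which.max(depths)]
  }
  list(owner = owner, assembly = engine$genome$assembly,
       variants = list(list(chrom = v$chrom, pos = v$pos,
                            ref = v$ref, alt = v$alt)),
       hpo_terms = as.list(terms))
}
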