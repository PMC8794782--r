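# small builders shared across the suite ------------------------------------

# AIL genotypes on a compact map; defaults sized for fast unit tests
small_ail <- function(n = 150, n_gen = 9, n_chr = 2, n_mark = 40,
                      chr_len = 1e8, seed = 1) {
  chrs <- setNames(rep(chr_len, n_chr), paste0("chr", seq_len(n_chr)))
  simulate_ail_genotypes(
    ail_design(n, n_gen, chrs, even_marker_map(chrs, n_mark), seed = seed))
}

# genotype matrix from explicit codes (markers x individuals)
geno_from_codes <- function(codes, chr = "chr1", spacing = 1e6) {
  m <- nrow(codes)
  map <- data.frame(marker = sprintf("m%03d", seq_len(m)), chr = chr,
                    pos = seq_len(m) * spacing)
  geno_matrix(map, codes)
}

# independent HWE markers at p = 0.5 (no LD), as a geno_matrix
hwe_geno <- function(n_mark, n_ind, seed = 1) {
  set.seed(seed)
  codes <- matrix(stats::rbinom(n_mark * n_ind, 2, 0.5), n_mark, n_ind)
  geno_from_codes(codes)
}

pheno_table <- function(ids, ...) {
  data.frame(id = ids, ...)
}

# brute-force Benjamini-Hochberg step-up (independent oracle)
bh_brute <- function(p) {
  n <- length(p)
  o <- order(p)
  adj <- p[o] * n / seq_len(n)
  for (i in (n - 1):1) adj[i] <- min(adj[i], adj[i + 1])
  out <- numeric(n)
  out[o] <- pmin(adj, 1)
  out
}

fixture_path <- function(name) {
  system.file("extdata", name, package = "ailqtl", mustWork = TRUE)
}

read_gene_flag_fixture <- function() {
  d <- utils::read.delim(fixture_path("candidate_gene_flags.tsv"))
  flag_cols <- c("stop_gain_or_loss", "missense_in_domain", "sift_deleterious",
                 "sift_tolerated", "promoter_or_splice", "utr", "enhancer",
                 "ctcf")
  for (cl in c(flag_cols, "de_any", "kegg")) d[[cl]] <- as.logical(d[[cl]])
  attr(d, "flag_cols") <- flag_cols
  d
}

score_fixture_row <- function(row, flag_cols, scheme = scoring_scheme()) {
  flags <- setNames(as.logical(row[flag_cols]), flag_cols)
  score_gene(flags, row$de_any, row$kegg, scheme)
}
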