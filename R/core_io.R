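#' Genotype matrix container
#'
#' Biallelic SNP genotypes for an intercross between two inbred founder
#' lines, coded as the number of S1 (first-founder) alleles each individual
#' carries: 0 = S2/S2, 1 = heterozygous, 2 = S1/S1, `NA` = missing.
#' Positions are 1-based base pairs and markers are stored sorted by
#' (chromosome, position).
#'
#' @param map data.frame with columns `marker`, `chr`, `pos` (1-based bp).
#' @param geno integer matrix, markers x individuals, values in
#'   \{0, 1, 2, NA\}; row names must match `map$marker`, column names are
#'   individual ids.
#' @return An object of class `geno_matrix`: a list with elements `map` and
#'   `geno`.
#' @export
geno_matrix <- function(map, geno) {
  stopifnot(is.data.frame(map), all(c("marker", "chr", "pos") %in% names(map)))
  geno <- as.matrix(geno)
  if (nrow(map) != nrow(geno))
    stopf("map has %d markers but geno has %d rows", nrow(map), nrow(geno))
  if (anyDuplicated(map$marker))
    stopf("duplicate marker ids: %s",
          paste(unique(map$marker[duplicated(map$marker)]), collapse = ", "))
  bad <- !(geno %in% c(0L, 1L, 2L) | is.na(geno))
  if (any(bad)) stopf("genotype codes must be 0, 1, 2 or NA")
  storage.mode(geno) <- "integer"
  rownames(geno) <- map$marker
  if (is.null(colnames(geno)))
    colnames(geno) <- paste0("ind", seq_len(ncol(geno)))
  # canonical marker order: by chromosome then position
  ord <- order(factor(map$chr, levels = unique(map$chr)), map$pos)
  map <- map[ord, , drop = FALSE]
  geno <- geno[ord, , drop = FALSE]
  rownames(map) <- NULL
  structure(list(map = map, geno = geno), class = "geno_matrix")
}

#' @export
print.geno_matrix <- function(x, ...) {
  cat(sprintf("<geno_matrix> %d markers x %d individuals on %d chromosome(s)\n",
              nrow(x$geno), ncol(x$geno), length(unique(x$map$chr))))
  invisible(x)
}

#' @export
dim.geno_matrix <- function(x) dim(x$geno)

#' Subset a genotype matrix by markers and/or individuals
#'
#' @param g A [geno_matrix()].
#' @param markers,individuals character vectors of marker / individual ids
#'   (NULL keeps all).
#' @return A `geno_matrix`.
#' @export
subset_geno <- function(g, markers = NULL, individuals = NULL) {
  stopifnot(inherits(g, "geno_matrix"))
  keep_m <- if (is.null(markers)) rep(TRUE, nrow(g$geno)) else g$map$marker %in% markers
  keep_i <- if (is.null(individuals)) rep(TRUE, ncol(g$geno)) else
    colnames(g$geno) %in% individuals
  if (!any(keep_m)) stopf("no markers left after subsetting")
  if (!any(keep_i)) stopf("no individuals left after subsetting")
  geno_matrix(g$map[keep_m, , drop = FALSE], g$geno[keep_m, keep_i, drop = FALSE])
}

# ---------------------------------------------------------------------------
# genotype I/O

#' Read a genotype matrix
#'
#' Two dialects are supported. `tsv_matrix` is the canonical interchange
#' format: a tab-separated file with header `marker chr pos ind1 ind2 ...`
#' and genotype codes 0/1/2 (NA for missing). `vcf` reads a VCF 4.x file
#' (via the vcfR package) and converts each sample genotype to an S1-allele
#' count using the declared founder allele: `founder_s1` says, per variant
#' or globally, whether the S1 line carries the REF or the ALT allele.
#'
#' Unsorted input is sorted with a warning. For VCF, a sample genotype
#' containing an allele not matching either founder raises an error naming
#' the variant.
#'
#' @param path file path.
#' @param dialect `"tsv_matrix"` (default) or `"vcf"`.
#' @param founder_s1 for `dialect = "vcf"`: either a single `"ref"`/`"alt"`
#'   applied to all variants, or a data.frame with columns `marker` and
#'   `s1_allele` (`"ref"`/`"alt"`).
#' @return A [geno_matrix()].
#' @export
read_genotypes <- function(path, dialect = c("tsv_matrix", "vcf"),
                           founder_s1 = "alt") {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stopf("file not found: %s", path)
  if (dialect == "tsv_matrix") {
    d <- read.delim(path, check.names = FALSE, colClasses = NA)
    if (!all(c("marker", "chr", "pos") %in% names(d)[1:3]))
      stopf("genotype TSV must start with columns marker, chr, pos")
    inds <- names(d)[-(1:3)]
    geno <- as.matrix(d[, inds, drop = FALSE])
    map <- data.frame(marker = as.character(d$marker), chr = as.character(d$chr),
                      pos = as.numeric(d$pos))
    if (is.unsorted_map(map))
      warnf("markers in %s were not sorted by (chr, pos); sorting", basename(path))
    geno_matrix(map, geno)
  } else {
    read_genotypes_vcf(path, founder_s1)
  }
}

is.unsorted_map <- function(map) {
  any(unlist(lapply(split(map$pos, factor(map$chr, unique(map$chr))),
                    is.unsorted)))
}

read_genotypes_vcf <- function(path, founder_s1) {
  if (!requireNamespace("vcfR", quietly = TRUE))
    stopf("reading VCF requires the vcfR package")
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  ids <- fix[, "ID"]
  ids[is.na(ids) | ids == "."] <- paste0(fix[, "CHROM"], "_", fix[, "POS"])[is.na(ids) | ids == "."]
  if (is.data.frame(founder_s1)) {
    stopifnot(all(c("marker", "s1_allele") %in% names(founder_s1)))
    s1 <- founder_s1$s1_allele[match(ids, founder_s1$marker)]
    if (anyNA(s1)) stopf("founder_s1 missing for variant(s): %s",
                         paste(head(ids[is.na(s1)], 5), collapse = ", "))
  } else {
    s1 <- rep(match.arg(founder_s1, c("ref", "alt")), length(ids))
  }
  gt <- vcfR::extract.gt(v, element = "GT")
  code1 <- function(x, s1_is_alt) {
    if (is.na(x) || x %in% c(".", "./.", ".|.")) return(NA_integer_)
    al <- strsplit(gsub("\\|", "/", x), "/", fixed = TRUE)[[1]]
    if (!all(al %in% c("0", "1")))
      return(-1L)  # flagged below with the variant id
    n_alt <- sum(al == "1")
    if (s1_is_alt) n_alt else length(al) - n_alt
  }
  geno <- matrix(NA_integer_, nrow(gt), ncol(gt), dimnames = dimnames(gt))
  for (i in seq_len(nrow(gt))) {
    row <- vapply(gt[i, ], code1, integer(1), s1_is_alt = (s1[i] == "alt"))
    if (any(row == -1L, na.rm = TRUE))
      stopf("variant %s: allele not matching either founder (non-biallelic genotype)", ids[i])
    geno[i, ] <- row
  }
  map <- data.frame(marker = ids, chr = as.character(fix[, "CHROM"]),
                    pos = as.numeric(fix[, "POS"]))
  geno_matrix(map, geno)
}

#' Write a genotype matrix as TSV
#'
#' @param g A [geno_matrix()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_genotypes <- function(g, path) {
  stopifnot(inherits(g, "geno_matrix"))
  d <- cbind(g$map, as.data.frame(g$geno, check.names = FALSE))
  write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# ---------------------------------------------------------------------------
# phenotype I/O

#' Read / write a phenotype table
#'
#' A phenotype table is a data.frame with one row per individual: an `id`
#' column, numeric trait columns, and optional covariate/label columns
#' (`litter_size`, `subfamily`, `line`, `genotyped_by`). `genotyped_by`,
#' when present, must be one of `"array"`, `"targeted"`, `"none"`.
#'
#' @param path file path.
#' @return data.frame.
#' @export
read_phenotypes <- function(path) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  d <- read.delim(path, check.names = FALSE)
  validate_phenotypes(d)
}

#' @rdname read_phenotypes
#' @export
validate_phenotypes <- function(d) {
  if (!"id" %in% names(d)) stopf("phenotype table must have an `id` column")
  d$id <- as.character(d$id)
  if (anyDuplicated(d$id)) stopf("duplicate individual ids in phenotype table")
  if ("genotyped_by" %in% names(d)) {
    bad <- !d$genotyped_by %in% c("array", "targeted", "none")
    if (any(bad)) stopf("genotyped_by must be array/targeted/none (rows %s)",
                        paste(head(which(bad), 5), collapse = ", "))
  }
  d
}

#' @rdname read_phenotypes
#' @param d phenotype data.frame.
#' @export
write_phenotypes <- function(d, path) {
  validate_phenotypes(d)
  write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# ---------------------------------------------------------------------------
# variant annotations

.consequences <- c("stop_gain", "stop_loss", "missense", "promoter",
                   "splice_site", "utr", "enhancer", "ctcf_binding_site",
                   "other")

#' Read a variant annotation table
#'
#' One row per variant x consequence, in the style of a flattened VEP
#' report: columns `variant`, `chr`, `pos`, `gene`, `consequence`,
#' `in_functional_domain` (logical; missense only), `sift_class`
#' (`deleterious` / `tolerated` / `none`; missense only). Consequence
#' strings outside the known vocabulary are mapped to `"other"` with a
#' message reporting the count. A `sift_class` other than `"none"` on a
#' non-missense row, or `in_functional_domain = TRUE` on a non-missense
#' row, is a validation error listing the offending rows.
#'
#' @param path file path.
#' @return validated data.frame (class `variant_annotations`).
#' @export
read_variant_annotations <- function(path) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  d <- read.delim(path, check.names = FALSE)
  if (nrow(d) == 0) {
    warnf("variant annotation file %s has no rows", basename(path))
    d <- data.frame(variant = character(), chr = character(), pos = numeric(),
                    gene = character(), consequence = character(),
                    in_functional_domain = logical(), sift_class = character())
  }
  validate_variant_annotations(d)
}

#' @rdname read_variant_annotations
#' @param d annotation data.frame.
#' @export
validate_variant_annotations <- function(d) {
  need <- c("variant", "chr", "pos", "gene", "consequence")
  if (!all(need %in% names(d)))
    stopf("annotation table needs columns: %s", paste(need, collapse = ", "))
  if (is.null(d$in_functional_domain)) d$in_functional_domain <- FALSE
  if (is.null(d$sift_class)) d$sift_class <- "none"
  d$in_functional_domain <- as.logical(d$in_functional_domain)
  d$in_functional_domain[is.na(d$in_functional_domain)] <- FALSE
  d$sift_class[is.na(d$sift_class) | d$sift_class == ""] <- "none"
  unknown <- !d$consequence %in% .consequences
  if (any(unknown)) {
    message(sum(unknown), " unknown consequence string(s) mapped to 'other'")
    d$consequence[unknown] <- "other"
  }
  bad_sift <- d$sift_class != "none" & d$consequence != "missense"
  if (any(bad_sift))
    stopf("sift_class set on non-missense rows: %s",
          paste(head(which(bad_sift), 10), collapse = ", "))
  bad_dom <- d$in_functional_domain & d$consequence != "missense"
  if (any(bad_dom))
    stopf("in_functional_domain set on non-missense rows: %s",
          paste(head(which(bad_dom), 10), collapse = ", "))
  if (!all(d$sift_class %in% c("deleterious", "tolerated", "none")))
    stopf("sift_class must be deleterious, tolerated or none")
  class(d) <- c("variant_annotations", "data.frame")
  d
}

#' Read a gene model table
#'
#' Columns `gene`, `name`, `chr`, `start`, `end`, `biotype`; 1-based
#' inclusive coordinates, `start <= end` enforced.
#'
#' @param path file path.
#' @param protein_coding_only drop non-protein-coding biotypes.
#' @return data.frame.
#' @export
read_gene_models <- function(path, protein_coding_only = FALSE) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  d <- read.delim(path, check.names = FALSE)
  need <- c("gene", "name", "chr", "start", "end", "biotype")
  if (!all(need %in% names(d)))
    stopf("gene model table needs columns: %s", paste(need, collapse = ", "))
  if (any(d$start > d$end)) stopf("gene model rows with start > end")
  if (protein_coding_only) d <- d[d$biotype == "protein_coding", , drop = FALSE]
  d
}

# ---------------------------------------------------------------------------
# expression matrices

#' Expression matrix container
#'
#' Probe-level intensities with sample metadata, the shape of a two-line
#' microarray experiment: `values` is a probes x samples numeric matrix
#' (non-negative on the raw intensity scale), `probes` maps probe ids to
#' gene ids, `samples` carries per-sample `line` and `tissue` labels.
#'
#' @param values numeric matrix, probes x samples.
#' @param probes data.frame with columns `probe`, `gene`.
#' @param samples data.frame with columns `sample`, `line`, `tissue`.
#' @param log2_scale logical; whether `values` are already on the log2 scale.
#' @return An object of class `expr_matrix`.
#' @export
expr_matrix <- function(values, probes, samples, log2_scale = FALSE) {
  values <- as.matrix(values)
  stopifnot(is.data.frame(probes), all(c("probe", "gene") %in% names(probes)),
            is.data.frame(samples),
            all(c("sample", "line", "tissue") %in% names(samples)))
  if (nrow(values) != nrow(probes) || ncol(values) != nrow(samples))
    stopf("values must be probes x samples (%d x %d given, %d probes, %d samples)",
          nrow(values), ncol(values), nrow(probes), nrow(samples))
  if (!log2_scale && any(values < 0, na.rm = TRUE))
    stopf("raw intensities must be non-negative")
  rownames(values) <- probes$probe
  colnames(values) <- samples$sample
  structure(list(values = values, probes = probes, samples = samples,
                 log2_scale = log2_scale),
            class = "expr_matrix")
}

#' @export
print.expr_matrix <- function(x, ...) {
  cat(sprintf("<expr_matrix> %d probes x %d samples (%s scale); tissues: %s\n",
              nrow(x$values), ncol(x$values),
              if (x$log2_scale) "log2" else "intensity",
              paste(unique(x$samples$tissue), collapse = ", ")))
  invisible(x)
}

#' Read / write an expression matrix
#'
#' The expression TSV has header `probe gene sample1 sample2 ...`; the
#' companion samples TSV has columns `sample`, `line`, `tissue`.
#'
#' @param path expression TSV path.
#' @param samples_path samples TSV path.
#' @param log2_scale whether stored values are log2.
#' @return An [expr_matrix()].
#' @export
read_expression <- function(path, samples_path, log2_scale = FALSE) {
  d <- read.delim(path, check.names = FALSE)
  s <- read.delim(samples_path, check.names = FALSE)
  probes <- data.frame(probe = as.character(d$probe), gene = as.character(d$gene))
  vals <- as.matrix(d[, setdiff(names(d), c("probe", "gene")), drop = FALSE])
  s$sample <- as.character(s$sample)
  if (!setequal(colnames(vals), s$sample))
    stopf("sample ids in %s and %s disagree", basename(path), basename(samples_path))
  expr_matrix(vals[, s$sample, drop = FALSE], probes, s, log2_scale = log2_scale)
}

#' @rdname read_expression
#' @param x an [expr_matrix()].
#' @export
write_expression <- function(x, path, samples_path) {
  stopifnot(inherits(x, "expr_matrix"))
  d <- cbind(x$probes, as.data.frame(x$values, check.names = FALSE))
  write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(x$samples, samples_path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
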