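#' Write pooled read counts as a VCF with AD fields
#'
#' Emits a minimal VCF 4.2 with per-family FORMAT fields GT (left as
#' \code{./.}; pool genotypes carry no dosage call) and AD (ref,alt read
#' counts). Coordinates are the 1-based marker positions.
#'
#' @param counts a \code{read_counts} object (families x markers matrices).
#' @param marker_map data.frame with marker_id, chromosome, position, ref, alt.
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @export
write_vcf_counts <- function(counts, marker_map, path) {
  fams <- rownames(counts$ref)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               paste0("##contig=<ID=", unique(marker_map$chromosome), ">"),
               "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
               paste0("##FORMAT=<ID=AD,Number=R,Type=Integer,",
                      "Description=\"Allelic depths (ref,alt)\">"),
               paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                       "INFO", "FORMAT", fams), collapse = "\t")), con)
  for (j in seq_len(nrow(marker_map))) {
    cells <- paste0("./.:", counts$ref[, j], ",", counts$alt[, j])
    writeLines(paste(c(marker_map$chromosome[j], marker_map$position[j],
                       marker_map$marker_id[j], marker_map$ref[j],
                       marker_map$alt[j], ".", "PASS", ".", "GT:AD", cells),
                     collapse = "\t"), con)
  }
  invisible(path)
}

#' Read pooled read counts from a VCF with AD fields
#'
#' Parses a VCF 4.2 via \pkg{vcfR} and extracts per-sample ref/alt read
#' counts from the AD FORMAT field. Sites that are not biallelic SNPs are
#' rejected here, upstream of all filtering. GT dosages are ignored.
#'
#' @param path VCF file path.
#' @return list with \code{counts} (a \code{read_counts} object) and
#'   \code{marker_map}.
#' @export
read_vcf_counts <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(v@fix, stringsAsFactors = FALSE)
  biallelic <- !grepl(",", fix$ALT) & nchar(fix$REF) == 1L &
    nchar(fix$ALT) == 1L & fix$ALT != "."
  if (!all(biallelic)) {
    v <- v[biallelic, ]
    fix <- fix[biallelic, , drop = FALSE]
  }
  ad <- vcfR::extract.gt(v, element = "AD")
  ref <- vcfR::masplit(ad, record = 1L, sort = FALSE)
  alt <- vcfR::masplit(ad, record = 2L, sort = FALSE)
  ref[is.na(ref)] <- 0; alt[is.na(alt)] <- 0
  mm <- data.frame(marker_id = fix$ID, chromosome = fix$CHROM,
                   position = as.integer(fix$POS), ref = fix$REF,
                   alt = fix$ALT, stringsAsFactors = FALSE)
  no_id <- is.na(mm$marker_id) | mm$marker_id == "."
  mm$marker_id[no_id] <- paste0(mm$chromosome[no_id], "_", mm$position[no_id])
  out <- list(ref = t(ref), alt = t(alt))
  dimnames(out$ref) <- dimnames(out$alt) <- list(colnames(ad), mm$marker_id)
  storage.mode(out$ref) <- storage.mode(out$alt) <- "integer"
  class(out) <- "read_counts"
  list(counts = out, marker_map = mm)
}

#' Read a tab-separated ref/alt count table
#'
#' Long format with header: marker, family, ref, alt.
#'
#' @param path TSV path.
#' @return a \code{read_counts} object.
#' @export
read_count_tsv <- function(path) {
  d <- read.delim(path, stringsAsFactors = FALSE)
  stopifnot(all(c("marker", "family", "ref", "alt") %in% names(d)))
  fams <- unique(d$family); mks <- unique(d$marker)
  ref <- alt <- matrix(0L, length(fams), length(mks),
                       dimnames = list(fams, mks))
  ref[cbind(d$family, d$marker)] <- as.integer(d$ref)
  alt[cbind(d$family, d$marker)] <- as.integer(d$alt)
  out <- list(ref = ref, alt = alt)
  class(out) <- "read_counts"
  out
}

#' Read a long-format individual phenotype TSV
#'
#' Header: individual_id, family_id, block, trait, value.
#' @param path TSV path.
#' @return data.frame.
#' @export
read_phenotypes_tsv <- function(path) {
  d <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("individual_id", "family_id", "block", "trait", "value")
  if (!all(need %in% names(d)))
    stop("phenotype table must have columns: ", paste(need, collapse = ", "))
  d$value <- as.numeric(d$value)
  d
}

#' Read a gene annotation BED file
#'
#' BED is 0-based half-open; coordinates are converted to 1-based inclusive
#' internally. The name column is expected as \code{geneid_copyindex}
#' (e.g. \code{G0012_2}); a bare gene id implies copy 1.
#'
#' @param path BED path (3+ columns, tab-separated, no header).
#' @return data.frame with gene_id, copy_index, chromosome, start, end.
#' @export
read_gene_bed <- function(path) {
  d <- read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  if (ncol(d) < 4L) d$V4 <- paste0("gene", seq_len(nrow(d)))
  name <- d[[4]]
  has_copy <- grepl("_[0-9]+$", name)
  gene_id <- ifelse(has_copy, sub("_[0-9]+$", "", name), name)
  copy <- ifelse(has_copy, as.integer(sub(".*_", "", name)), 1L)
  data.frame(gene_id = gene_id, copy_index = copy, chromosome = d[[1]],
             start = as.integer(d[[2]]) + 1L, end = as.integer(d[[3]]),
             stringsAsFactors = FALSE)
}

write_gene_bed <- function(genes, path) {
  bed <- data.frame(genes$chromosome, genes$start - 1L, genes$end,
                    paste0(genes$gene_id, "_", genes$copy_index))
  write.table(bed, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}

#' Read a genes-by-samples expression TSV
#' @param path TSV with a header row of sample names and gene ids in the
#'   first column.
#' @return numeric matrix (genes x samples).
#' @export
read_expression_tsv <- function(path) {
  d <- read.delim(path, row.names = 1L, check.names = FALSE)
  as.matrix(d)
}

#' Read a gene-to-term map TSV (columns gene_id, term)
#' @param path TSV path.
#' @return data.frame.
#' @export
read_term_map_tsv <- function(path) {
  d <- read.delim(path, stringsAsFactors = FALSE)
  stopifnot(all(c("gene_id", "term") %in% names(d)))
  d
}

# full-precision numeric formatting so matrices round-trip exactly
fmt_num <- function(x) sprintf("%.17g", x)

write_matrix_tsv <- function(m, path) {
  out <- cbind(id = rownames(m), as.data.frame(apply(m, 2, fmt_num)))
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write every fixture file for one simulated study
#'
#' Emits the VCF (with AD), long phenotype TSV, gene BED, expression TSV,
#' term-map TSV and ground-truth JSON into a directory. Reading the files
#' back reproduces the generated matrices exactly.
#'
#' @param study output of \code{\link{simulate_study}}.
#' @param dir output directory (created if absent).
#' @return named character vector of file paths, invisibly.
#' @export
write_fixtures <- function(study, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  p <- c(vcf = file.path(dir, "pools.vcf"),
         pheno = file.path(dir, "phenotypes.tsv"),
         bed = file.path(dir, "genes.bed"),
         expr = file.path(dir, "expression.tsv"),
         terms = file.path(dir, "term_map.tsv"),
         truth = file.path(dir, "ground_truth.json"))
  write_vcf_counts(study$counts, study$marker_map, p[["vcf"]])
  ph <- study$individuals
  ph$value <- fmt_num(ph$value)
  write.table(ph, p[["pheno"]], sep = "\t", quote = FALSE, row.names = FALSE)
  write_gene_bed(study$genes, p[["bed"]])
  write_matrix_tsv(study$tpm, p[["expr"]])
  write.table(study$term_map, p[["terms"]], sep = "\t", quote = FALSE,
              row.names = FALSE)
  jsonlite::write_json(study$ground_truth, p[["truth"]], auto_unbox = TRUE,
                       digits = NA)
  invisible(p)
}
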