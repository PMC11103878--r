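#' Read and write interval sets as BED
#'
#' Three-column BED (0-based half-open) with optional extra columns appended
#' after the coordinates. `read_bed` returns `chrom`, `start`, `end` plus any
#' named extra columns.
#'
#' @param x data frame with `chrom`, `start`, `end` (plus extras).
#' @param path file path.
#' @param extra_cols names of extra columns to write after the coordinates.
#' @return `write_bed` returns `path` invisibly.
#' @export
write_bed <- function(x, path, extra_cols = character(0)) {
  cols <- c("chrom", "start", "end", extra_cols)
  utils::write.table(x[, cols, drop = FALSE], path, sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname write_bed
#' @param col_names names for columns beyond the first three.
#' @export
read_bed <- function(path, col_names = character(0)) {
  x <- utils::read.table(path, sep = "\t", header = FALSE,
                         stringsAsFactors = FALSE)
  names(x) <- c("chrom", "start", "end",
                if (ncol(x) > 3) {
                  if (length(col_names) == ncol(x) - 3) col_names
                  else paste0("V", seq_len(ncol(x) - 3) + 3)
                })
  x
}

#' Write gene annotations as GFF3
#'
#' Minimal single-feature GFF3 (one `gene` row per record; GFF3 coordinates
#' are 1-based inclusive, converted from the package's 0-based half-open
#' intervals).
#'
#' @param genes data frame: `gene_id`, `chrom`, `start`, `end`.
#' @param path file path.
#' @return `path`, invisibly.
#' @export
write_gff3 <- function(genes, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("##gff-version 3", con)
  rows <- sprintf("%s\tchromadapt\tgene\t%d\t%d\t.\t+\t.\tID=%s",
                  genes$chrom, genes$start + 1L, genes$end, genes$gene_id)
  writeLines(rows, con)
  invisible(path)
}

#' Read and write dense contact matrices
#'
#' Tab-separated dense text matrix with a JSON sidecar (`<path>.json`) holding
#' the chromosome id and bin size.
#'
#' @param mat square contact matrix with a `bin_size` attribute (or pass
#'   `bin_size`).
#' @param path file path.
#' @param chrom chromosome id recorded in the sidecar.
#' @param bin_size bin size in bp (defaults to the matrix attribute).
#' @return `write_contact_matrix` returns `path` invisibly;
#'   `read_contact_matrix` returns the matrix with `chrom`/`bin_size`
#'   attributes restored.
#' @export
write_contact_matrix <- function(mat, path, chrom,
                                 bin_size = attr(mat, "bin_size")) {
  if (is.null(bin_size)) stopf("bin_size is required")
  utils::write.table(as.matrix(mat), path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  jsonlite::write_json(list(chrom = chrom, bin_size = bin_size,
                            n_bins = nrow(mat)),
                       paste0(path, ".json"), auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_contact_matrix
#' @export
read_contact_matrix <- function(path) {
  m <- as.matrix(utils::read.table(path, sep = "\t", header = FALSE))
  dimnames(m) <- NULL
  sidecar <- paste0(path, ".json")
  if (file.exists(sidecar)) {
    meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
    attr(m, "bin_size") <- meta$bin_size
    attr(m, "chrom") <- meta$chrom
  }
  m
}

#' Write a TSV table
#'
#' @param x data frame.
#' @param path file path.
#' @return `path`, invisibly.
#' @export
write_tsv <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_tsv
#' @export
read_tsv <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE)
}

#' Export a synthetic study to disk
#'
#' Writes the generated genome (GFF3 + BED), homoeolog pair map, sample sheet,
#' count/FPKM matrices, truth tables, per-sample TAD sets (BED) and contact
#' matrices (dense text + JSON sidecar), and the configuration (YAML) under
#' one directory.
#'
#' @param study a [simulate_study()] result.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_simulation <- function(study, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  g <- study$genome
  write_gff3(g$genes, file.path(dir, "genes.gff3"))
  write_bed(cbind(g$genes[, c("chrom", "start", "end")],
                  name = g$genes$gene_id),
            file.path(dir, "genes.bed"), extra_cols = "name")
  write_tsv(g$pairs, file.path(dir, "homoeolog_pairs.tsv"))
  write_tsv(study$expression$meta, file.path(dir, "samples.tsv"))
  utils::write.table(study$expression$counts, file.path(dir, "counts.tsv"),
                     sep = "\t", quote = FALSE)
  utils::write.table(round(study$expression$fpkm, 4),
                     file.path(dir, "fpkm.tsv"), sep = "\t", quote = FALSE)
  write_tsv(study$expression$truth$de, file.path(dir, "truth_de.tsv"))
  if (!is.null(study$expression$truth$bias))
    write_tsv(study$expression$truth$bias, file.path(dir, "truth_bias.tsv"))
  write_tsv(study$contacts$truth$events, file.path(dir, "truth_events.tsv"))
  mat_dir <- file.path(dir, "matrices")
  dir.create(mat_dir, showWarnings = FALSE)
  for (key in names(study$contacts$samples)) {
    s <- study$contacts$samples[[key]]
    write_bed(s$tads, file.path(dir, sprintf("tads_%s.bed", key)))
    for (ch in names(s$matrices))
      write_contact_matrix(s$matrices[[ch]],
                           file.path(mat_dir, sprintf("%s_%s.matrix", key, ch)),
                           chrom = ch)
  }
  write_sim_config(study$genome$config, file.path(dir, "config.yaml"))
  invisible(dir)
}
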