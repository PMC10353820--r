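#' Read a gene x sample counts TSV
#'
#' Genes as rows (first column = gene ID), header row of sample IDs.
#'
#' @param path file path.
#' @return Integer matrix with gene rownames and sample colnames.
#' @export
read_counts_tsv <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t", row.names = 1,
                          check.names = FALSE)
  as.matrix(df)
}

#' Write a gene x sample counts TSV
#' @param counts matrix with dimnames.
#' @param path file path.
#' @export
write_counts_tsv <- function(counts, path) {
  df <- data.frame(gene = rownames(counts), counts, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' Read sample metadata CSV (requires `sample_id` column)
#' @param path file path.
#' @return data.frame.
#' @export
read_metadata_csv <- function(path) {
  md <- utils::read.csv(path, stringsAsFactors = FALSE)
  assert_that("sample_id" %in% names(md), "metadata must have a sample_id column")
  md
}

#' Read gene sets in GMT format
#'
#' Tab-separated lines: term ID, description, then member genes.
#'
#' @param path file path.
#' @return Named list of gene vectors; descriptions in
#'   `attr(, "descriptions")`.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  sets <- lapply(parts, function(p) p[-(1:2)])
  names(sets) <- vapply(parts, `[`, "", 1L)
  attr(sets, "descriptions") <- stats::setNames(
    vapply(parts, `[`, "", 2L), names(sets))
  sets
}

#' Write gene sets in GMT format
#' @param sets named list of gene vectors.
#' @param path file path.
#' @param descriptions optional named descriptions (defaults to set names).
#' @export
write_gmt <- function(sets, path, descriptions = NULL) {
  if (is.null(descriptions)) descriptions <- names(sets)
  lines <- vapply(seq_along(sets), function(i) {
    paste(c(names(sets)[i], descriptions[i], sets[[i]]), collapse = "\t")
  }, "")
  writeLines(lines, path)
}

#' Read a BED-like file (0-based half-open)
#'
#' Tab-separated, no header; `track`/`browser`/comment lines are skipped.
#' Columns beyond the third are named by `extra`.
#'
#' @param path file path.
#' @param extra names for columns 4+ (e.g. `"state"` for a segmentation,
#'   `"value"` for a bedGraph, `c("gene_id", "score", "strand")` for genes).
#' @return data.frame with `chrom`, `start`, `end` and the extra columns.
#' @export
read_bed <- function(path, extra = character()) {
  lines <- readLines(path)
  keep <- !grepl("^(track|browser|#)", lines) & nzchar(lines)
  df <- utils::read.table(text = lines[keep], sep = "\t",
                          stringsAsFactors = FALSE)
  names(df)[1:3] <- c("chrom", "start", "end")
  if (length(extra))
    names(df)[3 + seq_along(extra)] <- extra
  df
}

#' Write a BED-like file (0-based half-open)
#' @param df data.frame starting with `chrom`, `start`, `end`.
#' @param path file path.
#' @export
write_bed <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
}

#' Read an SD/mean matrix TSV written by [write_sd_matrix()]
#' @param sd_path,mean_path file paths (explicit `NA` token for missing).
#' @param labels optional study label data.frame.
#' @return An `sd_matrix`.
#' @export
read_sd_matrix <- function(sd_path, mean_path = NULL, labels = NULL) {
  sd_mat <- as.matrix(utils::read.table(sd_path, header = TRUE, sep = "\t",
                                        row.names = 1, check.names = FALSE,
                                        na.strings = "NA"))
  mean_mat <- if (is.null(mean_path)) sd_mat else
    as.matrix(utils::read.table(mean_path, header = TRUE, sep = "\t",
                                row.names = 1, check.names = FALSE,
                                na.strings = "NA"))
  structure(list(sd = sd_mat, mean = mean_mat, labels = labels),
            class = "sd_matrix")
}

#' Write the SD (or mean) matrix as TSV with an explicit NA token
#' @param sd an `sd_matrix`.
#' @param sd_path,mean_path output paths (`mean_path` optional).
#' @export
write_sd_matrix <- function(sd, sd_path, mean_path = NULL) {
  wr <- function(m, p) {
    df <- data.frame(gene = rownames(m), m, check.names = FALSE)
    utils::write.table(df, p, sep = "\t", quote = FALSE, row.names = FALSE,
                       na = "NA")
  }
  wr(sd$sd, sd_path)
  if (!is.null(mean_path)) wr(sd$mean, mean_path)
  invisible(sd)
}

#' Write a gene_summary as TSV (gene, mean, sd, n)
#' @param summary a `gene_summary`.
#' @param path file path.
#' @export
write_gene_summary <- function(summary, path) {
  utils::write.table(summary, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(summary)
}

#' Read a gene_summary TSV
#' @param path file path.
#' @param study_id study identifier to record.
#' @return A `gene_summary`.
#' @export
read_gene_summary <- function(path, study_id) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  structure(df, class = c("gene_summary", "data.frame"), study_id = study_id)
}

#' Write every artifact of a simulated panel to a directory
#'
#' Emits per-study counts TSVs and one metadata CSV, the truth record as a
#' flat TSV, a config echo file, gene sets as GMT, binary labels as
#' two-column TSVs, environment responsiveness as TSV, window track as
#' bedGraph and segmentation/regions as BED.
#'
#' @param sim result of [generate_multistudy_counts()].
#' @param dir output directory (created if needed).
#' @param annotations optional [generate_annotations()] result.
#' @param tracks optional [generate_genomic_tracks()] result.
#' @return `dir`, invisibly.
#' @export
write_simulation <- function(sim, dir, annotations = NULL, tracks = NULL) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  md_all <- list()
  for (b in sim$studies) {
    write_counts_tsv(b$counts, file.path(dir, paste0(b$study_id, "_counts.tsv")))
    md <- b$metadata
    md$study_id <- b$study_id
    md_all[[b$study_id]] <- md
  }
  utils::write.csv(do.call(rbind, md_all), file.path(dir, "metadata.csv"),
                   row.names = FALSE)
  truth <- sim$truth
  tr <- data.frame(gene = names(truth$true_log_mean),
                   true_log_mean = truth$true_log_mean,
                   shared_propensity = truth$shared_propensity,
                   truth$realized_propensity, check.names = FALSE)
  utils::write.table(tr, file.path(dir, "truth.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  cfg <- truth$config
  writeLines(paste(names(cfg),
                   vapply(cfg, function(x) paste(x, collapse = ","), ""),
                   sep = "\t"),
             file.path(dir, "config_echo.tsv"))
  if (!is.null(annotations)) {
    write_gmt(annotations$terms, file.path(dir, "terms.gmt"))
    for (lab in names(annotations$labels)) {
      utils::write.table(
        data.frame(gene = annotations$labels[[lab]], label = 1L),
        file.path(dir, paste0("label_", lab, ".tsv")),
        sep = "\t", quote = FALSE, row.names = FALSE)
    }
    env <- annotations$env_response
    utils::write.table(data.frame(gene = rownames(env), env + 0L),
                       file.path(dir, "env_response.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  if (!is.null(tracks)) {
    write_bed(tracks$track, file.path(dir, "track.bedgraph"))
    write_bed(tracks$segmentation, file.path(dir, "segmentation.bed"))
    write_bed(tracks$regions[, c("chrom", "start", "end", "gene_id",
                                 "strand")],
              file.path(dir, "genes.bed"))
  }
  invisible(dir)
}
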