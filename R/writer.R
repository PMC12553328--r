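# Streaming single-writer for prediction records.
#
# All output rows pass through one writer object owned by the coordinating
# process: a full score file (every scored pair) and a positives file
# (score >= threshold). Rows are written as whole lines, so files are never
# interleaved or torn regardless of how many scoring workers ran.

prediction_writer <- function(output_prefix, threshold) {
  full_path <- paste0(output_prefix, ".tsv")
  pos_path <- paste0(output_prefix, ".positive.tsv")
  dir <- dirname(full_path)
  if (!dir.exists(dir)) {
    stop("output directory does not exist: ", dir, call. = FALSE)
  }
  full_con <- file(full_path, open = "wt")
  pos_con <- tryCatch(file(pos_path, open = "wt"),
                      error = function(e) { close(full_con); stop(e) })
  header <- "id1\tid2\tscore"
  writeLines(header, full_con)
  writeLines(header, pos_con)

  w <- new.env(parent = emptyenv())
  w$n_written <- 0L
  w$n_positive <- 0L
  w$write <- function(records) {
    if (nrow(records) == 0L) return(invisible(NULL))
    lines <- sprintf("%s\t%s\t%.6f", records$id1, records$id2, records$score)
    writeLines(lines, full_con)
    pos <- records$score >= threshold
    if (any(pos)) writeLines(lines[pos], pos_con)
    w$n_written <- w$n_written + nrow(records)
    w$n_positive <- w$n_positive + as.integer(sum(pos))
    invisible(NULL)
  }
  w$close <- function() {
    close(full_con)
    close(pos_con)
    list(full = full_path, positive = pos_path,
         n_written = w$n_written, n_positive = w$n_positive)
  }
  w
}

#' Write prediction records to disk
#'
#' Writes the full score TSV (`<prefix>.tsv`: columns `id1`, `id2`, `score`,
#' one header line, scores with 6 decimal places) and the positives TSV
#' (`<prefix>.positive.tsv`: rows with `score >= threshold`). The engine
#' streams through the same single-writer path; this standalone form writes
#' a complete record set at once.
#'
#' @param records data.frame with columns `id1`, `id2`, `score`.
#' @param threshold Positive-call threshold in [0, 1] (or above 1 to call
#'   nothing positive).
#' @param output_prefix Path prefix for the two files.
#' @return List with `full`, `positive` (paths), `n_written`, `n_positive`.
#' @export
write_predictions <- function(records, threshold, output_prefix) {
  stopifnot(is.data.frame(records),
            all(c("id1", "id2", "score") %in% names(records)))
  w <- prediction_writer(output_prefix, threshold)
  w$write(records)
  w$close()
}

#' Read a prediction TSV written by the engine
#'
#' @param path A `<prefix>.tsv` or `<prefix>.positive.tsv` file.
#' @return data.frame with columns `id1`, `id2`, `score`.
#' @export
read_predictions <- function(path) {
  utils::read.delim(path, header = TRUE, sep = "\t",
                    colClasses = c("character", "character", "numeric"),
                    stringsAsFactors = FALSE)
}
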