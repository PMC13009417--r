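# Delimited-text serialization of an EHR bundle. The five tables are plain
# CSVs with a header row and integer day offsets from the epoch
# (day 0 = 2010-01-01); the ground truth travels as JSON.

BUNDLE_TABLES <- c("demographics", "encounters", "prescriptions", "vitals",
                   "conditions", "death")

#' Write an EHR bundle to a directory of CSV files
#'
#' @param bundle an `ehr_bundle`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_bundle <- function(bundle, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (tb in BUNDLE_TABLES) {
    data.table::fwrite(as.data.table(bundle[[tb]]),
                       file.path(dir, paste0(tb, ".csv")))
  }
  if (!is.null(bundle$truth)) {
    tr <- bundle$truth
    long <- CJ(arm = tr$arms, month = tr$months, sorted = FALSE)
    long[, `:=`(mean = true_value(tr, arm, month, "mean"),
                contrast = true_value(tr, arm, month, "contrast"),
                risk = true_value(tr, arm, month, "risk"))]
    jsonlite::write_json(
      list(arms = tr$arms, reference = tr$reference, months = tr$months,
           p_obesity = tr$p_obesity, values = long),
      file.path(dir, "ground_truth.json"), digits = NA, dataframe = "columns")
  }
  invisible(dir)
}

#' Read an EHR bundle from a directory of CSV files
#'
#' @param dir directory produced by [write_bundle()].
#' @return an `ehr_bundle` (with `truth` when `ground_truth.json` exists).
#' @export
read_bundle <- function(dir) {
  out <- lapply(BUNDLE_TABLES, function(tb) {
    f <- file.path(dir, paste0(tb, ".csv"))
    if (!file.exists(f)) stop2("bundle table missing: ", f)
    # blank cells in the delimited files are missing values (e.g. sex/race)
    data.table::fread(f, na.strings = c("", "NA"))
  })
  names(out) <- BUNDLE_TABLES
  truth <- NULL
  tf <- file.path(dir, "ground_truth.json")
  if (file.exists(tf)) {
    j <- jsonlite::read_json(tf, simplifyVector = TRUE)
    v <- as.data.table(j$values)
    dn <- list(j$arms, as.character(j$months))
    tomat <- function(col) {
      m <- matrix(NA_real_, length(j$arms), length(j$months), dimnames = dn)
      m[cbind(v$arm, as.character(v$month))] <- v[[col]]
      m
    }
    truth <- structure(list(arms = j$arms, reference = j$reference,
                            months = j$months, mean = tomat("mean"),
                            contrast = tomat("contrast"), risk = tomat("risk"),
                            p_obesity = j$p_obesity),
                       class = "ground_truth")
  }
  structure(c(out, list(truth = truth, config = NULL)), class = "ehr_bundle")
}

#' Per-arm trajectory plot of standardized mean weight change
#'
#' Base-graphics small-multiple plot of the standardized monthly
#' weight-change curve per arm (with bootstrap bands when a
#' `bootstrap_result` is supplied alongside).
#'
#' @param result a `trial_result` (for the monthly `curve`).
#' @param file optional path; when given, a PNG is written there.
#' @return invisibly, the curve table.
#' @export
plot_trajectories <- function(result, file = NULL) {
  curve <- result$curve
  arms <- unique(curve$arm)
  if (!is.null(file)) {
    grDevices::png(file, width = 1200, height = 800, res = 120)
    on.exit(grDevices::dev.off())
  }
  op <- graphics::par(mfrow = c(ceiling(length(arms) / 4), 4),
                      mar = c(3, 3, 2, 1), mgp = c(2, 0.7, 0))
  on.exit(graphics::par(op), add = TRUE)
  ylim <- range(curve$mean_change, 0)
  for (a in arms) {
    d <- curve[arm == a]
    graphics::plot(d$month, d$mean_change, type = "l", lwd = 2, col = "navy",
         ylim = ylim, xlab = "month since initiation",
         ylab = "weight change (kg)", main = a)
    graphics::abline(h = 0, lty = 2, col = "grey50")
  }
  invisible(curve)
}
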