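#' Read an association-results table
#'
#' Reads a CSV/TSV file of per-variable association statistics into the
#' results data frame consumed by [align_results()]. The delimiter is
#' sniffed from the extension (`.tsv`/`.tab` = tab, otherwise comma)
#' unless `delim` is given. Rows with unparseable numbers are kept with
#' the offending value set missing and a warning; they are never dropped
#' silently. A mandatory column that is absent raises a schema error
#' naming it.
#'
#' At least one of the P-value and -log10 P columns must be present; when
#' both are, the supplied -log10 P wins for bubble sizing (it may encode
#' values below the smallest representable double) and a discrepancy
#' larger than 0.01 against `-log10(p)` triggers a warning.
#'
#' @param path File path.
#' @param id_col,est_col,se_col,p_col,neglogp_col Column names in the
#'   file for the variable identifier, effect estimate, standard error
#'   (optional), P-value and -log10 P-value.
#' @param delim Field delimiter override (`","` or `"\t"`).
#' @return A data frame of class `bubble_results` with columns
#'   `variable_id`, `estimate`, `se`, `p`, `neglog10p`.
#' @examples
#' f <- tempfile(fileext = ".csv")
#' write.csv(data.frame(id = c("a", "b"), beta = c(0.5, -1), pval = c(0.01, 0.2)),
#'           f, row.names = FALSE)
#' read_results(f, id_col = "id", est_col = "beta", p_col = "pval")
#' @export
read_results <- function(path, id_col = "variable_id",
                         est_col = "estimate", se_col = "se",
                         p_col = "p", neglogp_col = "neglog10p",
                         delim = NULL) {
  if (!file.exists(path))
    bg_stop(paste("results file not found:", path), "bg_io_error")
  if (is.null(delim)) {
    delim <- if (grepl("\\.(tsv|tab)$", path, ignore.case = TRUE)) "\t" else ","
  }
  raw <- utils::read.csv(path, sep = delim, stringsAsFactors = FALSE,
                         colClasses = "character", check.names = FALSE)
  have <- names(raw)
  miss <- setdiff(c(id_col, est_col), have)
  if (!(p_col %in% have) && !(neglogp_col %in% have))
    miss <- c(miss, paste0(p_col, " (or ", neglogp_col, ")"))
  if (length(miss))
    bg_stop(paste("results file missing mandatory columns:",
                  paste(miss, collapse = ", ")))

  num <- function(col) {
    if (!(col %in% have)) return(rep(NA_real_, nrow(raw)))
    x <- suppressWarnings(as.numeric(raw[[col]]))
    bad <- is.na(x) & !is.na(raw[[col]]) &
      !toupper(trimws(raw[[col]])) %in% c("", "NA", "NAN")
    if (any(bad)) {
      warning(sprintf("column '%s': %d unparseable value(s) set to NA (rows %s)",
                      col, sum(bad),
                      paste(utils::head(which(bad), 5), collapse = ", ")),
              call. = FALSE)
    }
    x
  }
  out <- data.frame(
    variable_id = as.character(raw[[id_col]]),
    estimate = num(est_col),
    se = num(se_col),
    p = num(p_col),
    neglog10p = num(neglogp_col),
    stringsAsFactors = FALSE
  )
  both <- !is.na(out$p) & !is.na(out$neglog10p)
  if (any(both)) {
    d <- abs(neglog10(out$p[both]) - out$neglog10p[both])
    if (any(d > 0.01))
      warning(sprintf("%d row(s) where -log10(p) and the supplied score disagree by > 0.01",
                      sum(d > 0.01)), call. = FALSE)
  }
  fill <- is.na(out$neglog10p) & !is.na(out$p)
  out$neglog10p[fill] <- neglog10(out$p[fill])
  class(out) <- c("bubble_results", class(out))
  out
}

#' Align association results to a catalog's template grids
#'
#' Matches each result row to a catalog variable (via [resolve_ids()]) and
#' populates every template grid with per-cell colour values (estimates)
#' and size values (-log10 P, stored uncapped so one aligned dataset can
#' render under different caps). Cells with no matched result, or with no
#' usable size value, are masked and draw no bubble. Unmatched inputs and
#' unfilled template entries are reported, with a warning, but never fail
#' the alignment: partial (legacy) datasets are expected.
#'
#' @param cat A `bubble_catalog`.
#' @param results A `bubble_results` data frame (or any data frame with
#'   columns `variable_id`, `estimate`, `neglog10p`).
#' @param keyspace,mapping Identifier resolution, as in [resolve_ids()].
#' @return An object of class `bubble_aligned`: list with `grids` (named
#'   list of `aligned_grid`, each holding `grid`, `color`, `size`, `mask`
#'   matrices), `report` (list with `unmatched_inputs`,
#'   `unfilled_template`, `n_input`, `n_matched`) and `catalog_name`.
#' @examples
#' cat225 <- load_template("nh225")
#' res <- generate_results("nh225", seed = 1)
#' al <- align_results(cat225, res)
#' al$report$n_matched
#' @export
align_results <- function(cat, results, keyspace = "nh_name",
                          mapping = NULL) {
  stopifnot(inherits(cat, "bubble_catalog"))
  if (!is.data.frame(results) || nrow(results) == 0)
    bg_stop("`results` must be a non-empty data frame")
  need <- c("variable_id", "estimate", "neglog10p")
  miss <- setdiff(need, names(results))
  if (length(miss))
    bg_stop(paste("results lack columns:", paste(miss, collapse = ", ")))

  res <- resolve_ids(cat, results$variable_id, keyspace, mapping)
  vid <- rep(NA_character_, nrow(results))
  hit <- match(results$variable_id, names(res$map))
  vid[!is.na(hit)] <- unname(res$map[hit[!is.na(hit)]])

  dup <- unique(vid[!is.na(vid) & duplicated(vid)])
  if (length(dup)) {
    bg_stop(paste("duplicate result rows for variable(s):",
                  paste(dup, collapse = ", ")))
  }
  matched <- !is.na(vid)
  est <- stats::setNames(results$estimate[matched], vid[matched])
  sco <- stats::setNames(results$neglog10p[matched], vid[matched])

  grids <- lapply(cat$grids, function(g) {
    idx <- match(g$cells, names(est))
    color <- matrix(est[idx], nrow = nrow(g$cells))
    size <- matrix(sco[idx], nrow = nrow(g$cells))
    mask <- !nzchar(g$cells) | is.na(idx) | is.na(size)
    structure(list(grid = g, color = color, size = size, mask = mask),
              class = "aligned_grid")
  })
  unfilled <- setdiff(cat$variables$variable_id, vid[matched])
  report <- list(unmatched_inputs = results$variable_id[!matched],
                 unfilled_template = unfilled,
                 n_input = nrow(results), n_matched = sum(matched))
  if (length(report$unmatched_inputs))
    warning(sprintf("%d input row(s) matched no catalog variable",
                    length(report$unmatched_inputs)), call. = FALSE)
  if (length(unfilled))
    warning(sprintf("%d catalog variable(s) received no result",
                    length(unfilled)), call. = FALSE)
  structure(list(grids = grids, report = report, catalog_name = cat$name),
            class = "bubble_aligned")
}

#' @export
print.bubble_aligned <- function(x, ...) {
  cat(sprintf("<bubble_aligned vs '%s': %d/%d rows matched, %d unfilled>\n",
              x$catalog_name, x$report$n_matched, x$report$n_input,
              length(x$report$unfilled_template)))
  invisible(x)
}
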