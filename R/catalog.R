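#' @title Variable catalogs
#' @description Packaged and user-defined catalogs describing which
#'   variable occupies which cell of which grid, plus the figure layout.
#' @name catalog
NULL

nh_template_names <- c("nh251", "nh249", "nh225")

template_path <- function(...) {
  system.file("extdata", "templates", ..., package = "bubblegrid",
              mustWork = FALSE)
}

#' Load a packaged or user-defined variable catalog
#'
#' The packaged catalogs cover the Nightingale Health NMR metabolomics
#' panels: `"nh251"` (current 251-variable profile), `"nh225"` (legacy 225
#' panel) and `"nh249"` (legacy 249 panel, represented as the 251 layout
#' with the two post-2020 additions left as empty cells). Each defines 10
#' grids, the largest being the lipoprotein-subclass block of 14 subclass
#' rows by 12 repeated measures. Any other `name` is treated as the path
#' to a user catalog CSV in the same format (see Details).
#'
#' @details A catalog CSV needs columns `variable_id`, `display_name`,
#'   `group`, `grid`, `row_label`, `col_label`, and optionally `footnote`
#'   (logical) and `absent_249` (logical; packaged use only). Grids are
#'   assembled from the unique row/column labels of each `grid` value in
#'   order of first appearance; a cell not named by any row is empty. A
#'   layout JSON may accompany a user catalog (`layout` argument) with
#'   fields `canvas` (width, height), `placements` (array of
#'   `{grid, x, y}`), optional `legend` (`{x, y}`) and `footnote` text; if
#'   omitted, panels are stacked into columns automatically at render time.
#'
#' @param name `"nh251"`, `"nh249"`, `"nh225"`, or a path to a catalog CSV.
#' @param layout Optional path to a layout JSON (user catalogs only).
#' @return An object of class `bubble_catalog`: list with `name`,
#'   `variables` (data frame), `grids` (named list of `template_grid`),
#'   `layout`, and `keyspaces`.
#' @examples
#' cat251 <- load_template("nh251")
#' nrow(cat251$variables)
#' names(cat251$grids)
#' @export
load_template <- function(name, layout = NULL) {
  if (name %in% nh_template_names) {
    base <- if (identical(name, "nh225")) "nh225" else "nh251"
    vars <- read_catalog_csv(template_path(paste0(base, "_variables.csv")))
    lay <- nh_layout(base)
    keyspaces <- nh_keyspaces(vars)
    if (identical(name, "nh249")) {
      # keep the 251 grid shapes; the two post-2020 additions become
      # empty cells rather than missing rows
      drop <- vars$variable_id[vars$absent_249]
      cat <- build_catalog(vars, lay, name, keyspaces, blank = drop)
    } else {
      cat <- build_catalog(vars, lay, name, keyspaces)
    }
    return(cat)
  }
  if (!file.exists(name)) {
    bg_stop(sprintf(
      "unknown template '%s': not one of %s and not an existing file",
      name, paste(nh_template_names, collapse = ", ")), "bg_notfound_error")
  }
  vars <- read_catalog_csv(name)
  lay <- if (!is.null(layout)) read_layout_json(layout) else NULL
  cat <- build_catalog(vars, lay, tools::file_path_sans_ext(basename(name)),
                       list(nh_name = "identity"))
  rep <- validate_catalog(cat)
  if (nrow(rep) > 0) {
    bg_stop(paste0("invalid catalog '", name, "':\n",
                   paste(" -", rep$rule, ":", rep$detail, collapse = "\n")))
  }
  cat
}

read_catalog_csv <- function(path) {
  if (!file.exists(path)) bg_stop(paste("cannot read catalog:", path),
                                  "bg_io_error")
  vars <- utils::read.csv(path, stringsAsFactors = FALSE,
                          colClasses = "character")
  need <- c("variable_id", "display_name", "group", "grid", "row_label",
            "col_label")
  miss <- setdiff(need, names(vars))
  if (length(miss)) {
    bg_stop(paste("catalog file missing columns:",
                  paste(miss, collapse = ", ")))
  }
  vars$footnote <- if ("footnote" %in% names(vars))
    as.logical(vars$footnote) else FALSE
  vars$absent_249 <- if ("absent_249" %in% names(vars))
    as.logical(vars$absent_249) else FALSE
  vars
}

read_layout_json <- function(path) {
  if (!file.exists(path)) bg_stop(paste("cannot read layout:", path),
                                  "bg_io_error")
  lay <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.data.frame(lay$placements)) {
    lay$placements <- lay$placements[, c("grid", "x", "y"), drop = FALSE]
  }
  lay
}

nh_layout <- function(base) {
  read_layout_json(template_path(paste0(base, "_layout.json")))
}

nh_keyspaces <- function(vars) {
  ks <- list(nh_name = "identity")
  kf <- template_path("ukb_field_synthetic.csv")
  if (nzchar(kf) && file.exists(kf)) {
    map <- utils::read.csv(kf, stringsAsFactors = FALSE,
                           colClasses = "character")
    map <- map[map$variable_id %in% vars$variable_id, , drop = FALSE]
    ks$ukb_field <- stats::setNames(map$variable_id, map$external_id)
  }
  ks
}

## Build grids (row/col label order = order of first appearance) and wrap
## everything in the catalog object. `blank` names variables whose cells are
## kept in the grid shape but left empty (the 249-in-251 rendering).
build_catalog <- function(vars, layout, name, keyspaces, blank = character()) {
  grids <- list()
  for (g in unique(vars$grid)) {
    sub <- vars[vars$grid == g, , drop = FALSE]
    rows <- unique(sub$row_label)
    cols <- unique(sub$col_label)
    cells <- matrix("", nrow = length(rows), ncol = length(cols),
                    dimnames = NULL)
    ri <- match(sub$row_label, rows)
    ci <- match(sub$col_label, cols)
    cells[cbind(ri, ci)] <- sub$variable_id
    grids[[g]] <- structure(
      list(name = g, row_labels = rows, col_labels = cols, cells = cells),
      class = "template_grid")
  }
  if (length(blank)) {
    for (g in names(grids)) {
      m <- grids[[g]]$cells
      m[m %in% blank] <- ""
      grids[[g]]$cells <- m
    }
    vars <- vars[!vars$variable_id %in% blank, , drop = FALSE]
  }
  structure(list(name = name, variables = vars, grids = grids,
                 layout = layout, keyspaces = keyspaces),
            class = "bubble_catalog")
}

#' @export
print.bubble_catalog <- function(x, ...) {
  cat(sprintf("<bubble_catalog '%s': %d variables, %d grids>\n",
              x$name, nrow(x$variables), length(x$grids)))
  for (g in x$grids) {
    cat(sprintf("  %-34s %2d x %2d (%d filled)\n", g$name,
                nrow(g$cells), ncol(g$cells), sum(nzchar(g$cells))))
  }
  invisible(x)
}

#' Validate a variable catalog
#'
#' Checks the structural invariants of a catalog and returns a report of
#' every violation; it never throws. An empty report (zero rows) means the
#' catalog is valid.
#'
#' Rules checked: unique variable ids; non-empty groups; every variable
#' placed in exactly one cell of one grid; every non-empty cell naming a
#' known variable; unique grid names; cell matrices matching their label
#' dimensions; layout placements referring to existing grids.
#'
#' @param cat A `bubble_catalog`.
#' @return Data frame of class `bubble_validation` with columns `rule` and
#'   `detail`; zero rows iff valid.
#' @examples
#' nrow(validate_catalog(load_template("nh225")))  # 0
#' @export
validate_catalog <- function(cat) {
  out <- list()
  add <- function(rule, detail) out[[length(out) + 1L]] <<-
      data.frame(rule = rule, detail = detail, stringsAsFactors = FALSE)
  v <- cat$variables
  dup <- unique(v$variable_id[duplicated(v$variable_id)])
  if (length(dup)) add("duplicate-variable-id", paste(dup, collapse = ", "))
  nogrp <- v$variable_id[is.na(v$group) | !nzchar(v$group)]
  if (length(nogrp)) add("empty-group", paste(nogrp, collapse = ", "))

  gnames <- vapply(cat$grids, `[[`, "", "name")
  if (anyDuplicated(names(cat$grids)) || anyDuplicated(gnames))
    add("duplicate-grid-name",
        paste(unique(gnames[duplicated(gnames)]), collapse = ", "))

  placed <- character()
  for (g in cat$grids) {
    if (!is.matrix(g$cells) ||
        nrow(g$cells) != length(g$row_labels) ||
        ncol(g$cells) != length(g$col_labels)) {
      add("grid-dimension-mismatch",
          sprintf("%s: cells %s x %s vs %d row labels, %d col labels",
                  g$name, nrow(g$cells), ncol(g$cells),
                  length(g$row_labels), length(g$col_labels)))
      next
    }
    placed <- c(placed, g$cells[nzchar(g$cells)])
  }
  multi <- unique(placed[duplicated(placed)])
  if (length(multi))
    add("variable-in-multiple-cells", paste(multi, collapse = ", "))
  unknown <- setdiff(placed, v$variable_id)
  if (length(unknown))
    add("cell-names-unknown-variable", paste(unknown, collapse = ", "))
  unplaced <- setdiff(v$variable_id, placed)
  if (length(unplaced))
    add("variable-not-placed", paste(unplaced, collapse = ", "))

  if (!is.null(cat$layout)) {
    pg <- cat$layout$placements$grid
    bad <- setdiff(pg, names(cat$grids))
    if (length(bad))
      add("layout-unknown-grid", paste(bad, collapse = ", "))
  }
  rep <- if (length(out)) do.call(rbind, out)
  else data.frame(rule = character(), detail = character(),
                  stringsAsFactors = FALSE)
  class(rep) <- c("bubble_validation", class(rep))
  rep
}

#' @export
print.bubble_validation <- function(x, ...) {
  if (nrow(x) == 0) {
    cat("catalog valid: no violations\n")
  } else {
    cat(sprintf("%d violation(s):\n", nrow(x)))
    for (i in seq_len(nrow(x)))
      cat(sprintf(" - %s: %s\n", x$rule[i], x$detail[i]))
  }
  invisible(x)
}

#' Resolve external identifiers to catalog variable ids
#'
#' Translates identifiers from an external scheme (a "keyspace", e.g. UK
#' Biobank field ids) into the catalog's canonical variable ids using the
#' catalog's built-in keyspaces or a user-supplied two-column mapping file.
#' Unresolved ids are returned, never silently dropped; resolved plus
#' unresolved always partitions the input.
#'
#' @param cat A `bubble_catalog`.
#' @param ids Character vector of external identifiers.
#' @param keyspace Keyspace name; `"nh_name"` (the identity keyspace) is
#'   always available. Ignored in favour of `mapping` when that is given.
#' @param mapping Optional path to a CSV with header columns
#'   `external_id, variable_id` defining an ad-hoc keyspace.
#' @return List with `map` (named character vector, external id ->
#'   variable id) and `unresolved` (character vector).
#' @examples
#' cat225 <- load_template("nh225")
#' resolve_ids(cat225, c("HDL_C", "nonsense"), "nh_name")
#' @export
resolve_ids <- function(cat, ids, keyspace = "nh_name", mapping = NULL) {
  stopifnot(inherits(cat, "bubble_catalog"))
  ids <- as.character(ids)
  if (!is.null(mapping)) {
    if (!file.exists(mapping))
      bg_stop(paste("mapping file not found:", mapping), "bg_io_error")
    m <- utils::read.csv(mapping, stringsAsFactors = FALSE,
                         colClasses = "character")
    if (!all(c("external_id", "variable_id") %in% names(m)))
      bg_stop("mapping file needs header columns external_id, variable_id")
    lookup <- stats::setNames(m$variable_id, m$external_id)
  } else if (identical(keyspace, "nh_name")) {
    lookup <- stats::setNames(cat$variables$variable_id,
                              cat$variables$variable_id)
  } else if (keyspace %in% names(cat$keyspaces)) {
    lookup <- cat$keyspaces[[keyspace]]
  } else {
    bg_stop(sprintf("unknown keyspace '%s'; available: %s", keyspace,
                    paste(names(cat$keyspaces), collapse = ", ")))
  }
  hit <- lookup[ids]
  ok <- !is.na(hit) & hit %in% cat$variables$variable_id
  list(map = stats::setNames(unname(hit[ok]), ids[ok]),
       unresolved = ids[!ok])
}
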