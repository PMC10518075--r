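test_that("packaged templates load with the documented structure", {
  counts <- c(nh251 = 251, nh249 = 249, nh225 = 225)
  for (nm in names(counts)) {
    cat <- load_template(nm)
    expect_s3_class(cat, "bubble_catalog")
    expect_equal(nrow(cat$variables), counts[[nm]])
    expect_length(cat$grids, 10L)
    expect_identical(nrow(validate_catalog(cat)), 0L)
    # count conservation: variables = filled cells over all grids
    filled <- sum(vapply(cat$grids, function(g) sum(nzchar(g$cells)), 0))
    expect_equal(filled, counts[[nm]])
    main <- cat$grids[["Lipoprotein subclasses"]]
    expect_identical(dim(main$cells), c(14L, 12L))
  }
})

test_that("loading is repeatable and side-effect free", {
  a <- load_template("nh225")
  b <- load_template("nh225")
  expect_identical(a, b)
})

test_that("the nh249 catalog is the nh251 layout with two blanked cells", {
  c251 <- load_template("nh251")
  c249 <- load_template("nh249")
  expect_identical(names(c249$grids), names(c251$grids))
  for (g in names(c251$grids))
    expect_identical(dim(c249$grids[[g]]$cells), dim(c251$grids[[g]]$cells))
  blanked <- sum(vapply(names(c251$grids), function(g)
    sum(nzchar(c251$grids[[g]]$cells) & !nzchar(c249$grids[[g]]$cells)), 0))
  expect_identical(blanked, 2)
  expect_setdiff <- setdiff(c251$variables$variable_id,
                            c249$variables$variable_id)
  expect_length(expect_setdiff, 2L)
})

test_that("unknown template names raise a not-found error", {
  expect_error(load_template("nh9999"), "unknown template",
               class = "bg_notfound_error")
})

test_that("user catalogs load from CSV and invalid ones are rejected", {
  path <- write_toy_catalog(4, 3)
  cat <- load_template(path)
  expect_identical(nrow(cat$variables), 12L)
  expect_length(cat$grids, 1L)
  expect_identical(dim(cat$grids[[1]]$cells), c(4L, 3L))

  # malformed: same variable id in two rows -> validation error listing it
  df <- read.csv(path, stringsAsFactors = FALSE)
  df$variable_id[2] <- df$variable_id[1]
  bad <- tempfile(fileext = ".csv")
  write.csv(df, bad, row.names = FALSE)
  expect_error(load_template(bad), "duplicate-variable-id")

  # missing a mandatory column -> schema error naming it
  df2 <- read.csv(path, stringsAsFactors = FALSE)
  df2$group <- NULL
  bad2 <- tempfile(fileext = ".csv")
  write.csv(df2, bad2, row.names = FALSE)
  expect_error(load_template(bad2), "group")
})

test_that("validation reports constructed violations without throwing", {
  cat <- load_template("nh225")
  # a variable placed in a second grid
  cat$grids[["Cholesterol"]]$cells[1, 1] <- "XXL_VLDL_P"
  rep <- validate_catalog(cat)
  expect_gt(nrow(rep), 0)
  expect_true(any(rep$rule == "variable-in-multiple-cells" &
                    grepl("XXL_VLDL_P", rep$detail)))

  # dimension mismatch between cells and labels
  cat2 <- load_template("nh225")
  cat2$grids[[2]]$col_labels <- c(cat2$grids[[2]]$col_labels, "extra",
                                  "more", "cols", "here")
  rep2 <- validate_catalog(cat2)
  expect_true(any(rep2$rule == "grid-dimension-mismatch"))

  # a cell naming an unknown variable
  cat3 <- load_template("nh225")
  cat3$grids[["Amino acids"]]$cells[1, 1] <- "NO_SUCH_VAR"
  rep3 <- validate_catalog(cat3)
  expect_true(any(rep3$rule == "cell-names-unknown-variable" &
                    grepl("NO_SUCH_VAR", rep3$detail)))
})

test_that("resolve_ids partitions input into resolved and unresolved", {
  cat <- load_template("nh225")
  ids <- cat$variables$variable_id
  r <- resolve_ids(cat, ids, "nh_name")
  expect_identical(unname(r$map), ids)   # identity keyspace
  expect_length(r$unresolved, 0L)

  r2 <- resolve_ids(cat, c("no_such_field"), "ukb_field")
  expect_length(r2$map, 0L)
  expect_identical(r2$unresolved, "no_such_field")

  # 3-entry toy keyspace {A->x, B->y, C->z} over input [A, C, Q]:
  # by enumeration A and C resolve, Q does not
  toy <- write_toy_catalog(1, 3)
  catT <- load_template(toy)
  ids3 <- catT$variables$variable_id  # V_1_1, V_1_2, V_1_3
  mp <- write_toy_mapping(c(A = ids3[1], B = ids3[2], C = ids3[3]))
  r3 <- resolve_ids(catT, c("A", "C", "Q"), mapping = mp)
  expect_identical(r3$map, c(A = ids3[1], C = ids3[3]))
  expect_identical(r3$unresolved, "Q")
  # totality: resolved + unresolved partitions the input
  expect_identical(sort(c(names(r3$map), r3$unresolved)),
                   sort(c("A", "C", "Q")))

  expect_error(resolve_ids(cat, "x", "no_such_keyspace"), "nh_name")
})

test_that("the synthetic ukb_field keyspace resolves its entries", {
  cat <- load_template("nh251")
  ks <- cat$keyspaces$ukb_field
  expect_gt(length(ks), 0)
  r <- resolve_ids(cat, names(ks), "ukb_field")
  expect_length(r$unresolved, 0L)
  expect_true(all(r$map %in% cat$variables$variable_id))
})
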