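#' Effect profile for the synthetic results generator
#'
#' Parametrises [generate_results()]. The defaults emulate the qualitative
#' structure of the association of a CETP genetic score (scaled to higher
#' HDL cholesterol) with the Nightingale panel: positive base effects for
#' HDL-related measures, negative for VLDL- and triglyceride-related
#' ones, a smooth gradient across the 14 lipoprotein subclass rows, and
#' modest effects elsewhere. Effects are in SD units of the metabolite
#' per unit of score; exact magnitudes are illustrative, not estimates
#' from any cohort.
#'
#' @param base_effects Named numeric vector of per-group base effects
#'   (names match catalog `group` values; groups not named get
#'   `default_effect`).
#' @param default_effect Base effect for unnamed groups.
#' @param gradient Signed slope applied across the 14 subclass rows of the
#'   main lipoprotein block (units per row, centred on the block middle).
#' @param noise_sd Standard deviation of the per-variable noise added to
#'   the base effect (0 gives deterministic effects).
#' @param se Standard error attached to every estimate; smaller values
#'   push P-values lower (this is the knob controlling significance).
#' @return A list of class `effect_profile`.
#' @export
effect_profile <- function(base_effects = NULL, default_effect = 0,
                           gradient = 0.02, noise_sd = 0.04, se = 0.03) {
  if (is.null(base_effects)) {
    base_effects <- c(
      "VLDL subclasses" = -0.25,
      "IDL" = -0.05,
      "LDL subclasses" = -0.10,
      "HDL subclasses" = 0.30,
      "Lipoprotein particle sizes" = 0.10,
      "Apolipoproteins" = 0.05,
      "Cholesterol" = 0.08,
      "Other lipids" = -0.08,
      "Fatty acids" = -0.05,
      "Glycolysis" = -0.02,
      "Amino acids" = 0.02,
      "Ketone bodies" = 0.02,
      "Fluid balance" = 0.01,
      "Inflammation" = -0.06
    )
  }
  if (noise_sd < 0) bg_stop("`noise_sd` must be nonnegative")
  if (se <= 0) bg_stop("`se` must be positive")
  structure(list(base_effects = base_effects,
                 default_effect = default_effect,
                 gradient = gradient, noise_sd = noise_sd, se = se),
            class = "effect_profile")
}

#' Generate seeded synthetic association results for a template
#'
#' Produces exactly one record per catalog variable, with estimates drawn
#' from an [effect_profile()] and P-values derived from the two-sided
#' normal tail of `estimate / se`, so that estimate, SE, P and -log10 P
#' are mutually consistent. Results are reproducible per seed
#' (Mersenne-Twister RNG with inversion normal sampling); the caller's
#' RNG state is restored on exit.
#'
#' For variables in the lipoprotein-subclass main block, the profile
#' gradient shifts the effect linearly with the subclass row (top =
#' largest VLDL, bottom = smallest HDL), giving the smooth
#' across-subclass trends such data show in practice.
#'
#' @param template Template id or catalog path, as in [load_template()].
#' @param seed Integer seed.
#' @param profile An [effect_profile()].
#' @return A `bubble_results` data frame (one row per catalog variable).
#' @examples
#' res <- generate_results("nh225", seed = 1)
#' nrow(res)
#' @export
generate_results <- function(template, seed = 1, profile = effect_profile()) {
  stopifnot(inherits(profile, "effect_profile"))
  cat <- if (inherits(template, "bubble_catalog")) template
         else load_template(template)
  v <- cat$variables

  main <- cat$grids[["Lipoprotein subclasses"]]
  rowpos <- rep(0, nrow(v))
  if (!is.null(main)) {
    ri <- row(main$cells)[match(v$variable_id, main$cells)]
    centre <- (nrow(main$cells) + 1) / 2
    rowpos[!is.na(ri)] <- ri[!is.na(ri)] - centre
  }
  base <- unname(profile$base_effects[v$group])
  base[is.na(base)] <- profile$default_effect

  if (exists(".Random.seed", envir = globalenv())) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  }
  set.seed(seed, kind = "Mersenne-Twister", normal.kind = "Inversion")
  noise <- if (profile$noise_sd > 0)
    stats::rnorm(nrow(v), 0, profile$noise_sd) else rep(0, nrow(v))

  estimate <- base + profile$gradient * rowpos + noise
  se <- rep(profile$se, nrow(v))
  z <- abs(estimate) / se
  # keep P strictly inside (0, 1]: |z| beyond ~38.4 would underflow
  z <- pmin(z, 38)
  p <- 2 * stats::pnorm(-z)
  out <- data.frame(variable_id = v$variable_id,
                    estimate = estimate, se = se, p = p,
                    neglog10p = -log10(p),
                    stringsAsFactors = FALSE)
  class(out) <- c("bubble_results", class(out))
  out
}

#' Write results to a fixture CSV
#'
#' Writes a results table in the same schema [read_results()] reads by
#' default, with enough digits that estimates round-trip to within 1e-9
#' relative error. An empty table yields a header-only file.
#'
#' @param results A `bubble_results` data frame.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_fixture <- function(results, path) {
  dir <- dirname(path)
  if (!dir.exists(dir)) bg_stop(paste("no such directory:", dir),
                                "bg_io_error")
  df <- as.data.frame(results)
  for (col in c("estimate", "se", "p", "neglog10p")) {
    if (col %in% names(df)) df[[col]] <- formatC(df[[col]], digits = 15,
                                                 format = "g")
  }
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
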