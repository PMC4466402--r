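#' Configuration for the synthetic climate-scenario generator
#'
#' Describes a multi-layer climate simulation over a bounded grid: per-variable
#' spatial trends, smoothed noise, an "ocean" nodata mask shared by all layers
#' and scenarios, and one additive offset vector per past scenario (standing
#' for alternative general-circulation-model reconstructions of the Last
#' Glacial Maximum). Everything is a pure function of this configuration and
#' its seed.
#'
#' Default variables and units mirror a WorldClim-style bioclimatic subset for
#' tropical South America: `bio4` temperature seasonality (standard deviation
#' x 100), `bio8`/`bio9` mean temperature of the wettest/driest quarter
#' (degrees C x 10), `bio16`/`bio17` precipitation of the wettest/driest
#' quarter (mm). Values are kept in these raw layer units throughout — filter
#' widths and niche breadths are expressed in the same units.
#'
#' @param grid A `grid_spec`; defaults to a 100 x 100 half-degree window over
#'   tropical/subtropical South America.
#' @param variable_names Layer names.
#' @param base_levels Named per-variable mean level, raw layer units.
#' @param gradient_strengths Named per-variable magnitude of the linear
#'   spatial trend across the full grid extent, raw units.
#' @param noise_sd Named per-variable standard deviation of the smoothed
#'   noise field (the noise is rescaled after smoothing, so this is the
#'   realised, not pre-smoothing, SD). Defaults to half the gradient
#'   strength: each variable then carries substantial variation independent
#'   of the shared spatial trend, so no variable is a linear combination of
#'   the others — the property that makes "inert decoy" variables
#'   statistically distinguishable from truly active ones.
#' @param noise_scale Moving-average smoothing radius in cells (>= 0);
#'   controls the spatial autocorrelation length of the noise component.
#' @param lgm_offsets Named list of past scenarios, each a named per-variable
#'   additive shift (past minus present). The two defaults stand for two
#'   circulation models with a cooler, drier, more seasonal glacial climate.
#' @param mask_fraction Fraction of cells masked as ocean, in \[0, 1).
#' @param seed Integer seed; the generator is bit-reproducible given the
#'   configuration.
#' @return An object of class `climate_sim_config`.
#' @export
climate_sim_config <- function(
    grid = grid_spec(100, 100, x_origin = -80, y_origin = 10, cell_size = 0.5),
    variable_names = c("bio4", "bio8", "bio9", "bio16", "bio17"),
    base_levels = c(bio4 = 1500, bio8 = 240, bio9 = 220,
                    bio16 = 800, bio17 = 150),
    gradient_strengths = c(bio4 = 800, bio8 = 80, bio9 = 100,
                           bio16 = 600, bio17 = 250),
    noise_sd = NULL,
    noise_scale = 2,
    lgm_offsets = list(
      lgm_ccsm = c(bio4 = 150, bio8 = -35, bio9 = -40,
                   bio16 = -120, bio17 = -40),
      lgm_miroc = c(bio4 = 100, bio8 = -25, bio9 = -30,
                    bio16 = -180, bio17 = -20)),
    mask_fraction = 0.1,
    seed = 1L) {
  stopifnot(inherits(grid, "grid_spec"),
            mask_fraction >= 0, mask_fraction < 1, noise_scale >= 0)
  variable_names <- as.character(variable_names)
  take <- function(x, default_frac = NULL) {
    if (is.null(x)) x <- gradient_strengths[variable_names] * default_frac
    if (is.null(names(x))) names(x) <- variable_names
    miss <- setdiff(variable_names, names(x))
    if (length(miss)) stop("missing value for variable(s): ",
                           paste(miss, collapse = ", "))
    x[variable_names]
  }
  base_levels <- take(base_levels)
  gradient_strengths <- take(gradient_strengths)
  noise_sd <- take(noise_sd, default_frac = 0.5)
  lgm_offsets <- lapply(lgm_offsets, take)
  structure(list(grid = grid, variable_names = variable_names,
                 base_levels = base_levels,
                 gradient_strengths = gradient_strengths,
                 noise_sd = noise_sd, noise_scale = noise_scale,
                 lgm_offsets = lgm_offsets,
                 mask_fraction = mask_fraction, seed = as.integer(seed)),
            class = "climate_sim_config")
}

#' Generate a current climate stack plus past-scenario stacks
#'
#' Each layer is a smooth field: a linear spatial trend (direction varying by
#' variable) plus moving-average-smoothed white noise. Past scenarios are the
#' current fields shifted by the configured per-variable offsets, so the
#' present-vs-past contrast has a known, controllable effect size. All
#' scenarios share an identical ocean mask. Calling the generator twice with
#' the same configuration yields bit-identical stacks.
#'
#' @param cfg A `climate_sim_config`.
#' @return Named list of `env_stack` objects: `current` first, then one per
#'   entry of `cfg$lgm_offsets`.
#' @export
generate_scenarios <- function(cfg) {
  stopifnot(inherits(cfg, "climate_sim_config"))
  g <- cfg$grid
  if (g$n_rows < 4 || g$n_cols < 4)
    stop("degenerate grid: need at least 4 rows and 4 columns")
  nv <- length(cfg$variable_names)
  rf <- matrix((seq_len(g$n_rows) - 0.5) / g$n_rows, g$n_rows, g$n_cols)
  cf <- matrix((seq_len(g$n_cols) - 0.5) / g$n_cols, g$n_rows, g$n_cols,
               byrow = TRUE)
  fields <- with_seed(cfg$seed, {
    mask <- matrix(FALSE, g$n_rows, g$n_cols)
    n_mask <- round(cfg$mask_fraction * g$n_rows * g$n_cols)
    if (n_mask > 0)
      mask[sample.int(g$n_rows * g$n_cols, n_mask)] <- TRUE
    layers <- vector("list", nv)
    for (v in seq_len(nv)) {
      angle <- (v - 1) * 2 * pi / nv + pi / 7  # one trend direction per variable
      trend <- cfg$gradient_strengths[v] *
        (cos(angle) * (rf - 0.5) + sin(angle) * (cf - 0.5))
      noise <- smooth_matrix(
        matrix(stats::rnorm(g$n_rows * g$n_cols), g$n_rows, g$n_cols),
        cfg$noise_scale)
      if (cfg$noise_sd[v] > 0 && stats::sd(noise) > 0)
        noise <- noise * cfg$noise_sd[v] / stats::sd(noise)
      m <- cfg$base_levels[v] + trend + noise
      m[mask] <- NA_real_
      layers[[v]] <- m
    }
    layers
  })
  mk_stack <- function(offsets, scen) {
    rs <- lapply(seq_len(nv), function(v) {
      m <- fields[[v]] + offsets[v]
      env_raster(g, m, name = cfg$variable_names[v])
    })
    env_stack(rs, scenario_name = scen)
  }
  zero <- stats::setNames(rep(0, nv), cfg$variable_names)
  out <- c(list(current = mk_stack(zero, "current")),
           lapply(seq_along(cfg$lgm_offsets), function(i)
             mk_stack(cfg$lgm_offsets[[i]], names(cfg$lgm_offsets)[i])))
  names(out) <- c("current", names(cfg$lgm_offsets))
  out
}

#' A known ("true") species niche for virtual-species experiments
#'
#' A Gaussian bell response on each variable: suitability is the product over
#' variables of `exp(-0.5 ((x - optimum) / breadth)^2)`, scaled by
#' `max_suitability`. Breadths are in raw layer units.
#'
#' @param optima Named per-variable optimum values.
#' @param breadths Named per-variable tolerances (Gaussian SD), all > 0.
#' @param max_suitability Peak suitability, in (0, 1\].
#' @return An object of class `true_niche`.
#' @export
true_niche <- function(optima, breadths, max_suitability = 1) {
  stopifnot(!is.null(names(optima)), !is.null(names(breadths)),
            all(names(optima) %in% names(breadths)),
            all(breadths[names(optima)] > 0),
            max_suitability > 0, max_suitability <= 1)
  structure(list(optima = optima, breadths = breadths[names(optima)],
                 max_suitability = as.numeric(max_suitability)),
            class = "true_niche")
}

#' Evaluate a true niche over a climate stack
#'
#' @param niche A `true_niche`; its variables must all be layers of `stack`.
#' @param stack An `env_stack`.
#' @return An `env_raster` of suitability in \[0, 1\]; masked cells stay
#'   masked.
#' @export
true_suitability <- function(niche, stack) {
  stopifnot(inherits(niche, "true_niche"), inherits(stack, "env_stack"))
  miss <- setdiff(names(niche$optima), names(stack$layers))
  if (length(miss))
    stop("stack lacks niche variable(s): ", paste(miss, collapse = ", "))
  s <- matrix(niche$max_suitability, stack$spec$n_rows, stack$spec$n_cols)
  for (v in names(niche$optima)) {
    z <- (stack$layers[[v]]$values - niche$optima[[v]]) / niche$breadths[[v]]
    s <- s * exp(-0.5 * z^2)
  }
  env_raster(stack$spec, s, name = "suitability")
}

#' Sample presence-only occurrences from a suitability surface
#'
#' Cells are drawn with replacement with probability proportional to
#' suitability times an optional sampling-bias weight (1 where absent), and
#' each point is placed uniformly inside its drawn cell. Masked cells are
#' never drawn, so every occurrence falls on a valid cell.
#'
#' @param suit An `env_raster` of suitability in \[0, 1\].
#' @param n Number of records (>= 1).
#' @param bias Optional aligned `env_raster` of non-negative sampling-effort
#'   weights, emulating collection bias.
#' @param seed Integer seed.
#' @param species Species label for the output.
#' @return An `occurrence_set` with role `"raw"`.
#' @export
sample_occurrences <- function(suit, n, bias = NULL, seed = 1L,
                               species = "virtual") {
  stopifnot(inherits(suit, "env_raster"), n >= 1)
  w <- suit$values
  if (!is.null(bias)) {
    stopifnot(inherits(bias, "env_raster"), grids_aligned(suit$spec, bias$spec))
    w <- w * bias$values
  }
  idx <- which(!is.na(w) & w > 0)
  if (!length(idx)) stop("all sampling weights are zero or masked")
  with_seed(seed, {
    cells <- idx[sample.int(length(idx), n, replace = TRUE, prob = w[idx])]
    row <- (cells - 1L) %% suit$spec$n_rows + 1L
    col <- (cells - 1L) %/% suit$spec$n_rows + 1L
    cs <- suit$spec$cell_size
    # uniform position inside the half-open cell [west, east) x (south, north]
    lon <- suit$spec$x_origin + (col - 1L) * cs + stats::runif(n) * cs
    lat <- suit$spec$y_origin - (row - 1L) * cs - stats::runif(n) * cs
    occurrence_set(species, lon, lat,
                   source = rep("synthetic", n), role = "raw")
  })
}

#' Host-parasite coupling for virtual-species experiments
#'
#' The parasite's realised suitability is its climate-only suitability
#' multiplied by the host's suitability raised to `coupling_strength`:
#' strength 0 reduces the parasite to its climate-only niche, strength 1
#' makes the parasite fully track host availability.
#'
#' @param host_niche,parasite_niche `true_niche` objects.
#' @param coupling_strength Scalar in \[0, 1\].
#' @return An object of class `biotic_coupling`.
#' @export
biotic_coupling <- function(host_niche, parasite_niche, coupling_strength) {
  stopifnot(inherits(host_niche, "true_niche"),
            inherits(parasite_niche, "true_niche"),
            coupling_strength >= 0, coupling_strength <= 1)
  structure(list(host_niche = host_niche, parasite_niche = parasite_niche,
                 coupling_strength = as.numeric(coupling_strength)),
            class = "biotic_coupling")
}

#' Sample coupled host and parasite occurrence sets
#'
#' The host is sampled from its own climate suitability; the parasite from
#' climate suitability times host suitability to the power
#' `coupling_strength`. The host draw uses `seed` and the parasite draw
#' `seed + 1`, so at coupling 0 the parasite draw is identical to a
#' climate-only [sample_occurrences()] call with seed `seed + 1`.
#'
#' @param coupling A `biotic_coupling`.
#' @param stack An `env_stack` providing all niche variables.
#' @param n_host,n_parasite Record counts.
#' @param seed Integer seed.
#' @return List with `host` and `parasite` occurrence sets plus the two
#'   suitability rasters (`host_suitability`, `parasite_suitability`).
#' @export
sample_host_parasite <- function(coupling, stack, n_host, n_parasite,
                                 seed = 1L) {
  stopifnot(inherits(coupling, "biotic_coupling"))
  host_suit <- true_suitability(coupling$host_niche, stack)
  para_clim <- true_suitability(coupling$parasite_niche, stack)
  para_vals <- para_clim$values * host_suit$values ^ coupling$coupling_strength
  para_suit <- env_raster(stack$spec, para_vals, name = "suitability")
  list(
    host = sample_occurrences(host_suit, n_host, seed = seed,
                              species = "virtual_host"),
    parasite = sample_occurrences(para_suit, n_parasite, seed = seed + 1L,
                                  species = "virtual_parasite"),
    host_suitability = host_suit,
    parasite_suitability = para_suit
  )
}
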