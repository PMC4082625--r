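#' Configuration for the meiotic-cell simulator
#'
#' Describes the pachytene cells to simulate: one synaptonemal complex (SC)
#' per autosomal bivalent per cell, with MLH1 foci (crossovers) placed by a
#' weighted hard-core point process. Crossover interference is modelled as a
#' minimum spacing between foci (a fraction of SC length); the obligate
#' crossover is enforced by drawing per-SC counts from a zero-truncated
#' Poisson; suppression intervals (e.g. an inversion) multiply the placement
#' intensity by `suppression_factor`.
#'
#' @param n_cells Number of cells.
#' @param per_sc_expected_co Numeric vector: delivered expected crossovers per
#'   SC (one entry per SC/bivalent). The simulator calibrates the underlying
#'   Poisson rate so the realised mean matches this value under obligate
#'   crossover.
#' @param sc_length_um SC length in micrometres per bivalent; recycled.
#' @param centromere_rel_pos Centromere position as a fraction of SC length
#'   (in (0,1)); recycled.
#' @param interference_min_spacing Minimum distance between adjacent foci as a
#'   fraction of SC length (default 0.2).
#' @param obligate_co If `TRUE`, every SC carries at least one focus.
#' @param suppression_intervals Named list: for SC index `i` (name `"sc<i>"`
#'   or plain list position), a two-column matrix/list of relative intervals
#'   `[lo, hi]` in \[0,1\] where intensity is multiplied by
#'   `suppression_factor`. Use `NULL` for none.
#' @param suppression_factor Multiplier in \[0,1\] applied inside suppression
#'   intervals.
#' @param bac_markers Named list per SC: named numeric vector of marker
#'   positions as fractions of SC length, copied onto every simulated SC.
#' @param seed Integer seed.
#' @return List of class `synrec_meiosis_config`.
#' @export
meiosis_config <- function(n_cells = 100,
                           per_sc_expected_co = rep(1.76, 20),
                           sc_length_um = NULL,
                           centromere_rel_pos = 0.4,
                           interference_min_spacing = 0.2,
                           obligate_co = TRUE,
                           suppression_intervals = NULL,
                           suppression_factor = 1,
                           bac_markers = NULL,
                           seed = 1L) {
  n_sc <- length(per_sc_expected_co)
  if (is.null(sc_length_um)) {
    sc_length_um <- seq(18, 5, length.out = n_sc)
  }
  sc_length_um <- rep_len(sc_length_um, n_sc)
  centromere_rel_pos <- rep_len(centromere_rel_pos, n_sc)
  if (suppression_factor < 0 || suppression_factor > 1) {
    abort("suppression_factor must lie in [0, 1]")
  }
  if (any(centromere_rel_pos <= 0 | centromere_rel_pos >= 1)) {
    abort("centromere_rel_pos must lie strictly inside (0, 1)")
  }
  if (any(per_sc_expected_co < 0)) abort("per_sc_expected_co must be >= 0")
  if (!is.null(suppression_intervals)) {
    for (iv in suppression_intervals) {
      if (is.null(iv)) next
      m <- matrix(unlist(iv), ncol = 2, byrow = is.null(dim(iv)))
      if (any(m < 0 | m > 1) || any(m[, 1] >= m[, 2])) {
        abort("suppression intervals must be non-empty sub-intervals of [0, 1]")
      }
    }
  }
  structure(list(n_cells = as.integer(n_cells),
                 per_sc_expected_co = per_sc_expected_co,
                 sc_length_um = sc_length_um,
                 centromere_rel_pos = centromere_rel_pos,
                 interference_min_spacing = interference_min_spacing,
                 obligate_co = obligate_co,
                 suppression_intervals = suppression_intervals,
                 suppression_factor = suppression_factor,
                 bac_markers = bac_markers,
                 seed = as.integer(seed)),
            class = "synrec_meiosis_config")
}

#' Study-regime meiosis configuration
#'
#' Convenience constructor for the regime used throughout the worked
#' examples: 258 cells, 20 autosomal bivalents with lengths declining from
#' 18 to 5 um, per-SC crossover expectations increasing linearly with SC
#' length, scaled so they total `total_expected_co` (35.24 foci/cell) with a
#' floor just above the obligate single crossover.
#'
#' @param n_cells Number of cells (default 258).
#' @param n_sc Bivalents per cell (default 20).
#' @param total_expected_co Target mean total foci per cell.
#' @param seed Integer seed.
#' @return A [meiosis_config()].
#' @export
meiosis_config_study <- function(n_cells = 258, n_sc = 20,
                                 total_expected_co = 35.24, seed = 1L) {
  len <- seq(18, 5, length.out = n_sc)
  lo <- 1.1
  # lambda_i = lo + b * (len - min(len)), b chosen so sum = total
  b <- (total_expected_co - lo * n_sc) / sum(len - min(len))
  lam <- lo + b * (len - min(len))
  meiosis_config(n_cells = n_cells, per_sc_expected_co = lam,
                 sc_length_um = len, seed = seed)
}

# Poisson rate whose (zero-truncated, when obligate) mean equals m.
calibrate_rate <- function(m, obligate) {
  if (!obligate) return(m)
  if (m <= 1) {
    # obligate CO forces a mean of at least 1; deliver the floor
    return(1e-8)
  }
  uniroot(function(l) l / (1 - exp(-l)) - m,
          lower = 1e-8, upper = m, tol = 1e-10)$root
}

rztpois <- function(n, lambda) {
  if (lambda < 1e-6) return(rep(1L, n))
  # inverse-CDF on the truncated distribution
  u <- runif(n)
  qpois(stats::ppois(0, lambda) + u * (1 - stats::ppois(0, lambda)), lambda)
}

# Place n points in [0,1] with all pairwise gaps >= d, uniformly among valid
# configurations: order statistics on [0, 1-(n-1)d] plus the fixed gaps.
place_hardcore <- function(n, d) {
  if (n == 0L) return(numeric())
  slack <- 1 - (n - 1) * d
  stopifnot(slack > 0)
  sort(runif(n, 0, slack)) + d * (seq_len(n) - 1)
}

# Relative weight of position x under the suppression profile.
suppression_weight <- function(x, intervals, s) {
  w <- rep(1, length(x))
  if (!is.null(intervals)) {
    m <- matrix(unlist(intervals), ncol = 2, byrow = is.null(dim(intervals)))
    for (r in seq_len(nrow(m))) {
      w[x >= m[r, 1] & x < m[r, 2]] <- s
    }
  }
  w
}

# Fraction of intensity mass remaining after suppression.
suppressed_mass <- function(intervals, s) {
  if (is.null(intervals)) return(1)
  m <- matrix(unlist(intervals), ncol = 2, byrow = is.null(dim(intervals)))
  tot <- sum(m[, 2] - m[, 1])
  1 - tot * (1 - s)
}

simulate_one_sc <- function(lambda, d, obligate, intervals, s, max_try = 200L) {
  rho <- suppressed_mass(intervals, s)
  lam_eff <- lambda * rho
  max_n <- floor(1 / max(d, 1e-9) - 1e-9) + 1L  # largest n with positive slack
  n <- if (obligate) rztpois(1L, max(lam_eff, 1e-8)) else rpois(1L, lam_eff)
  n <- min(n, max_n)
  repeat {
    ok <- FALSE
    for (i in seq_len(max_try)) {
      x <- place_hardcore(n, d)
      w <- suppression_weight(x, intervals, s)
      if (all(runif(length(x)) < w)) { ok <- TRUE; break }
    }
    if (ok || n <= if (obligate) 1L else 0L) break
    n <- n - 1L  # unplaceable under the hard core / suppression: back off
  }
  if (!ok) x <- numeric()
  sort(x)
}

#' Simulate synaptonemal complexes with MLH1 foci
#'
#' One row per SC per cell. Foci are placed along the SC (positions in um) by
#' a hard-core point process: counts from a Poisson (zero-truncated when
#' `obligate_co`) whose rate is calibrated so the delivered per-SC mean equals
#' `per_sc_expected_co` (before suppression), positions uniform subject to the
#' interference spacing, thinned by the suppression profile.
#'
#' @param config A [meiosis_config()].
#' @return Tibble of class `synrec_cells`: `cell_id`, `sc_id`,
#'   `sc_length_um`, `centromere_um`, `foci_um` (list-column of sorted
#'   positions), `bac_markers` (list-column of named positions in um).
#' @export
simulate_meiotic_cells <- function(config) {
  stopifnot(inherits(config, "synrec_meiosis_config"))
  n_sc <- length(config$per_sc_expected_co)
  lam <- vapply(config$per_sc_expected_co, calibrate_rate,
                numeric(1), obligate = config$obligate_co)
  supp <- lapply(seq_len(n_sc), function(i) {
    si <- config$suppression_intervals
    if (is.null(si)) return(NULL)
    si[[paste0("sc", i)]] %||% if (i <= length(si) && is.null(names(si)))
      si[[i]] else NULL
  })
  bac <- lapply(seq_len(n_sc), function(i) {
    bm <- config$bac_markers
    if (is.null(bm)) return(NULL)
    bm[[paste0("sc", i)]] %||% if (i <= length(bm) && is.null(names(bm)))
      bm[[i]] else NULL
  })
  with_seed(derive_seed(config$seed, 2L), {
    rows <- vector("list", config$n_cells * n_sc)
    k <- 0L
    for (cell in seq_len(config$n_cells)) {
      for (i in seq_len(n_sc)) {
        L <- config$sc_length_um[i]
        rel <- simulate_one_sc(lam[i], config$interference_min_spacing,
                               config$obligate_co, supp[[i]],
                               config$suppression_factor)
        k <- k + 1L
        rows[[k]] <- tibble(
          cell_id = cell, sc_id = paste0("sc", i),
          sc_length_um = L,
          centromere_um = config$centromere_rel_pos[i] * L,
          foci_um = list(rel * L),
          bac_markers = list(if (is.null(bac[[i]])) setNames(numeric(),
                                                             character())
                             else bac[[i]] * L))
      }
    }
    out <- bind_rows(rows)
    class(out) <- c("synrec_cells", class(out))
    out
  })
}
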