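# Spatial correlation of mutation pairs within and between branches,
# model-based null spectra, and estimation of the follow-up parameters
# (epsilon, xi) of the exponential co-localization model
# p(x | x0) = epsilon * exp(-|x - x0| / xi).

# per-branch cached geometry: eligible positions (1-based), mu over them,
# mutated positions, and the (replicate-invariant) available-pair histogram
coloc_branch_data <- function(branches, model, r_max) {
  lapply(branches, function(b) {
    enc <- encode_seq(b$parent_seq)
    mu <- position_mutability(enc, model)
    eligible <- which(!is.na(mu) & mu > 0)
    ind <- numeric(if (length(eligible)) max(eligible) else 0L)
    ind[eligible] <- 1
    list(eligible = eligible, mu = mu,
         mut = b$events$x + 1L, n = b$n_mut,
         lineage_id = b$lineage_id,
         ind = ind, avail = avail_hist(ind, r_max))
  })
}

# pair-distance histogram of a position set (1-based), r = 1..r_max
pair_hist <- function(pos, r_max) {
  h <- numeric(r_max)
  if (length(pos) >= 2L) {
    d <- abs(outer(pos, pos, "-"))
    d <- d[upper.tri(d)]
    d <- d[d >= 1 & d <= r_max]
    if (length(d)) h <- tabulate(d, nbins = r_max)
  }
  h
}

# available-pair histogram of an indicator vector, r = 1..r_max
avail_hist <- function(ind, r_max) {
  n <- length(ind)
  vapply(seq_len(r_max), function(r)
    if (r >= n) 0 else sum(ind[1:(n - r)] * ind[(1 + r):n]), numeric(1))
}

# cross histograms between two branches (mutation pairs / available pairs)
cross_hists <- function(pos1, pos2, ind1, ind2, r_max) {
  num <- numeric(r_max)
  if (length(pos1) && length(pos2)) {
    d <- abs(outer(pos1, pos2, "-"))
    d <- d[d >= 1 & d <= r_max]
    if (length(d)) num <- tabulate(d, nbins = r_max)
  }
  n <- max(length(ind1), length(ind2))
  ind1 <- c(ind1, numeric(n - length(ind1)))
  ind2 <- c(ind2, numeric(n - length(ind2)))
  den <- vapply(seq_len(r_max), function(r) {
    if (r >= n) return(0)
    sum(ind1[1:(n - r)] * ind2[(1 + r):n]) +
      sum(ind2[1:(n - r)] * ind1[(1 + r):n])
  }, numeric(1))
  list(num = num, den = den)
}

# per-unit numerator/denominator contributions to the spectrum.
# within mode: one row per branch with >= 2 mutations.
# between mode: one row per unordered pair of distinct branches of the same
# lineage where both carry >= 1 mutation; rows are tagged by lineage.
spectrum_contributions <- function(bd, mode, r_max, mut_override = NULL) {
  muts <- if (is.null(mut_override)) lapply(bd, `[[`, "mut") else mut_override
  if (mode == "within_branch") {
    rows_num <- list(); rows_den <- list(); unit <- character(0)
    for (i in seq_along(bd)) {
      if (length(muts[[i]]) < 2L) next
      rows_num[[length(rows_num) + 1L]] <- pair_hist(muts[[i]], r_max)
      rows_den[[length(rows_den) + 1L]] <- bd[[i]]$avail
      unit <- c(unit, bd[[i]]$lineage_id)
    }
  } else {
    by_lineage <- split(seq_along(bd),
                        vapply(bd, `[[`, character(1), "lineage_id"))
    rows_num <- list(); rows_den <- list(); unit <- character(0)
    for (lid in names(by_lineage)) {
      idx <- by_lineage[[lid]]
      idx <- idx[vapply(idx, function(i) length(muts[[i]]) >= 1L, logical(1))]
      if (length(idx) < 2L) next
      for (a in seq_len(length(idx) - 1L)) {
        for (b in (a + 1L):length(idx)) {
          i <- idx[a]; j <- idx[b]
          ch <- cross_hists(muts[[i]], muts[[j]], bd[[i]]$ind, bd[[j]]$ind,
                            r_max)
          rows_num[[length(rows_num) + 1L]] <- ch$num
          rows_den[[length(rows_den) + 1L]] <- ch$den
          unit <- c(unit, lid)
        }
      }
    }
  }
  if (!length(rows_num))
    return(list(num = matrix(0, 0, r_max), den = matrix(0, 0, r_max),
                unit = character(0)))
  list(num = do.call(rbind, rows_num), den = do.call(rbind, rows_den),
       unit = unit)
}

#' Mutation pair-distance spectrum
#'
#' For each distance `r`, the number of mutation pairs at distance `r`
#' divided by the number of available eligible-position pairs at that
#' distance, summed over the contributing units. In `"within_branch"` mode
#' a unit is a branch carrying at least two mutations; in
#' `"between_branch"` mode a unit is an unordered pair of distinct branches
#' of the same lineage, each carrying at least one mutation, and pairs
#' combine one mutation from each branch.
#'
#' @param branches list of `shm_branch` objects (already filtered by the
#'   lineage-size and branch-length rules of [extract_mutation_events()]).
#' @param model a `mutability_model`, used only to determine position
#'   eligibility.
#' @param mode `"within_branch"` or `"between_branch"`.
#' @param r_max largest distance (nt).
#' @return data.frame with columns `r`, `n` (NA where no pairs are
#'   available).
#' @export
pair_distance_spectrum <- function(branches, model,
                                   mode = c("within_branch",
                                            "between_branch"),
                                   r_max = 100L) {
  mode <- match.arg(mode)
  bd <- coloc_branch_data(branches, model, r_max)
  sc <- spectrum_contributions(bd, mode, r_max)
  num <- colSums(sc$num); den <- colSums(sc$den)
  data.frame(r = seq_len(r_max), n = ifelse(den > 0, num / den, NA_real_))
}

#' Model-predicted pair-distance spectrum
#'
#' Re-simulates every branch's mutations under the fitted targeting model
#' (`epsilon = 0`, same parent sequence, same mutation count)
#' `n_replicates` times and computes the same spectrum; numerators are
#' averaged over replicates against the fixed denominators.
#'
#' @inheritParams pair_distance_spectrum
#' @param n_replicates number of simulation replicates.
#' @param seed RNG seed.
#' @param epsilon,xi optional follow-up parameters for simulating spectra
#'   under the co-localization model (used by [fit_colocalization()]).
#' @return data.frame with columns `r`, `n_m`.
#' @export
model_null_spectrum <- function(branches, model,
                                mode = c("within_branch", "between_branch"),
                                r_max = 100L, n_replicates = 20L,
                                seed = 1L, epsilon = 0, xi = 10) {
  mode <- match.arg(mode)
  set.seed(seed)
  bd <- coloc_branch_data(branches, model, r_max)
  num <- numeric(r_max); den <- numeric(r_max)
  for (rep in seq_len(n_replicates)) {
    muts <- lapply(bd, function(d)
      place_mutations(d$mu, d$eligible, d$n, epsilon = epsilon, xi = xi)$pos)
    sc <- spectrum_contributions(bd, mode, r_max, mut_override = muts)
    num <- num + colSums(sc$num); den <- den + colSums(sc$den)
  }
  data.frame(r = seq_len(r_max),
             n_m = ifelse(den > 0, num / den, NA_real_))
}

#' Co-localization correlation function f(r) = n(r) / n_m(r)
#'
#' Elementwise ratio of the observed spectrum to the model prediction, with
#' percentile bootstrap confidence bands obtained by resampling the
#' contributing units (branches within mode, lineages between mode) of the
#' observed spectrum; the model prediction is held fixed.
#'
#' @inheritParams pair_distance_spectrum
#' @param n_replicates replicates for the model spectrum.
#' @param n_boot bootstrap resamples for the confidence band.
#' @param seed RNG seed.
#' @return An object of class `correlation_profile`: data.frame with
#'   columns `r`, `n`, `n_m`, `f`, `ci_low`, `ci_high`, and attribute
#'   `mode`.
#' @export
correlation_function <- function(branches, model,
                                 mode = c("within_branch", "between_branch"),
                                 r_max = 100L, n_replicates = 20L,
                                 n_boot = 100L, seed = 1L) {
  mode <- match.arg(mode)
  bd <- coloc_branch_data(branches, model, r_max)
  sc <- spectrum_contributions(bd, mode, r_max)
  num <- colSums(sc$num); den <- colSums(sc$den)
  n <- ifelse(den > 0, num / den, NA_real_)
  nm <- model_null_spectrum(branches, model, mode, r_max, n_replicates,
                            seed = seed)$n_m
  f <- ifelse(!is.na(n) & !is.na(nm) & nm > 0, n / nm, NA_real_)
  # unit-level bootstrap of the observed spectrum
  units <- unique(sc$unit)
  set.seed(seed + 1L)
  fb <- matrix(NA_real_, n_boot, r_max)
  if (length(units) >= 2L && nrow(sc$num) > 0) {
    unit_of <- match(sc$unit, units)
    for (b in seq_len(n_boot)) {
      pick <- sample.int(length(units), replace = TRUE)
      w <- tabulate(pick, nbins = length(units))[unit_of]
      nb <- colSums(sc$num * w); db <- colSums(sc$den * w)
      fb[b, ] <- ifelse(db > 0 & !is.na(nm) & nm > 0,
                        (nb / db) / nm, NA_real_)
    }
  }
  ci <- apply(fb, 2, function(col)
    if (all(is.na(col))) c(NA_real_, NA_real_)
    else quantile(col, c(0.025, 0.975), na.rm = TRUE, names = FALSE))
  out <- data.frame(r = seq_len(r_max), n = n, n_m = nm, f = f,
                    ci_low = ci[1, ], ci_high = ci[2, ])
  attr(out, "mode") <- mode
  class(out) <- c("correlation_profile", "data.frame")
  out
}

#' Expected follow-up mutations per targeting event
#'
#' Closed form for the interior-position approximation of the follow-up
#' model: the number of follow-ups after one targeted mutation is
#' approximately Poisson with mean `2 epsilon / (1 - exp(-1 / xi))`.
#'
#' @param epsilon follow-up amplitude, `>= 0`.
#' @param xi correlation length (nt), `> 0`.
#' @return Expected follow-up count.
#' @export
expected_followups <- function(epsilon, xi) {
  stopifnot(epsilon >= 0)
  if (xi <= 0) stop("xi must be positive")
  2 * epsilon / (1 - exp(-1 / xi))
}

#' Grid estimation of the follow-up parameters
#'
#' Simulates the within-branch correlation function under each candidate
#' `(epsilon, xi)` with the observed branch structure, and returns the grid
#' point minimizing the squared distance to the observed `f(r)`.
#'
#' @param f_observed a `correlation_profile` (within-branch mode) or a
#'   numeric vector `f(r)` on `r = 1..r_max`.
#' @param branches,model as in [pair_distance_spectrum()].
#' @param epsilon_grid,xi_grid candidate values.
#' @param r_max distances used in the objective.
#' @param n_replicates simulation replicates per grid point.
#' @param seed RNG seed.
#' @return list with `epsilon`, `xi`, and the `surface` data.frame
#'   (epsilon, xi, distance).
#' @export
fit_colocalization <- function(f_observed, branches, model,
                               epsilon_grid = c(0, 0.025, 0.05, 0.075, 0.1),
                               xi_grid = c(5, 10, 20),
                               r_max = 50L, n_replicates = 20L, seed = 1L) {
  if (is.data.frame(f_observed)) f_observed <- f_observed$f
  stopifnot(length(f_observed) >= r_max)
  nm <- model_null_spectrum(branches, model, "within_branch", r_max,
                            n_replicates, seed = seed)$n_m
  grid <- expand.grid(epsilon = epsilon_grid, xi = xi_grid)
  dist2 <- numeric(nrow(grid))
  for (k in seq_len(nrow(grid))) {
    ns <- model_null_spectrum(branches, model, "within_branch", r_max,
                              n_replicates, seed = seed + k,
                              epsilon = grid$epsilon[k], xi = grid$xi[k])$n_m
    fs <- ifelse(!is.na(ns) & !is.na(nm) & nm > 0, ns / nm, NA_real_)
    ok <- is.finite(fs) & is.finite(f_observed[seq_len(r_max)])
    dist2[k] <- mean((fs[ok] - f_observed[seq_len(r_max)][ok])^2)
  }
  best <- which.min(dist2)
  list(epsilon = grid$epsilon[best], xi = grid$xi[best],
       surface = cbind(grid, distance = dist2))
}

#' Write a correlation profile as TSV
#' @param profile a `correlation_profile`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_correlation_profile <- function(profile, path) {
  out <- cbind(as.data.frame(profile), mode = attr(profile, "mode"))
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
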