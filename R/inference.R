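# Maximum-likelihood inference of the factorized mutability model
#
#   mu_{s,x} = gamma_{w(s,x)} * beta_x ,   <beta_x> = 1
#
# from per-branch mutation events. Each comparable position carries an
# independent Poisson mutation clock with rate mu over the branch length t,
# so a branch contributes
#
#   sum_{mutated x} log(1 - exp(-mu t)) - sum_{unmutated x} mu t
#     = sum_{mutated x} log(exp(mu t) - 1) - sum_{all x} mu t .
#
# The stationarity condition in gamma_w (beta fixed) decouples across
# contexts and is solved by bracketed one-dimensional root finding; likewise
# for beta_x with gamma fixed. Alternating the two full updates is
# coordinate ascent on the joint likelihood and converges monotonically.

#' Construct a mutability model
#'
#' @param gamma numeric vector of 5-mer rate multipliers; either length 1024
#'   in [all_fivemers()] order or named by 5-mer (missing contexts become
#'   `NA`).
#' @param beta numeric vector of position rate multipliers (0-based position
#'   `x` is entry `x + 1`); undefined positions `NA`.
#' @param normalize rescale so `mean(beta, na.rm = TRUE) == 1`, compensating
#'   in `gamma` (likelihood-invariant). Default `FALSE`: simulation truths
#'   are taken as given.
#' @return An object of class `mutability_model` with elements `gamma`
#'   (named, length 1024), `beta`, `L`.
#' @export
mutability_model <- function(gamma, beta, normalize = FALSE) {
  fm <- all_fivemers()
  g <- setNames(rep(NA_real_, 1024L), fm)
  if (is.null(names(gamma))) {
    stopifnot(length(gamma) == 1024L)
    g[] <- gamma
  } else {
    idx <- fivemer_index(names(gamma))
    g[idx] <- gamma
  }
  stopifnot(all(is.na(g) | g >= 0), all(is.na(beta) | beta >= 0))
  if (normalize) {
    sc <- mean(beta, na.rm = TRUE)
    beta <- beta / sc
    g <- g * sc
  }
  structure(list(gamma = g, beta = as.numeric(beta),
                 L = length(beta)), class = "mutability_model")
}

# ---- sufficient statistics -------------------------------------------------

# per-branch eligible positions: 0-based x with full A/C/G/T parent 5-mer,
# A/C/G/T child base, x < L
branch_positions <- function(branch, L) {
  pe <- encode_seq(branch$parent_seq)
  ce <- encode_seq(branch$child_seq)
  ctx <- context_indices(pe)
  x0 <- seq_along(pe) - 1L
  el <- !is.na(ctx) & !is.na(ce) & x0 < L
  list(w = ctx[el], x = x0[el] + 1L,            # x is 1-based into beta
       mut = pe[el] != ce[el], to = ce[el])
}

# Exposure matrix T[w, x] = summed branch length t over occurrences of
# context w at position x, plus the per-mutation records.
branch_stats <- function(branches, L) {
  Tm <- matrix(0, 1024L, L)
  nb <- length(branches)
  mw <- vector("list", nb); mx <- vector("list", nb)
  mt <- vector("list", nb); mto <- vector("list", nb)
  for (i in seq_len(nb)) {
    b <- branches[[i]]
    p <- branch_positions(b, L)
    if (b$t > 0) {
      ii <- cbind(p$w, p$x)
      Tm[ii] <- Tm[ii] + b$t
    }
    if (any(p$mut)) {
      mw[[i]] <- p$w[p$mut]; mx[[i]] <- p$x[p$mut]
      mt[[i]] <- rep(b$t, sum(p$mut)); mto[[i]] <- p$to[p$mut]
    }
  }
  list(T = Tm,
       mut = data.frame(w = unlist(mw), x = unlist(mx), t = unlist(mt),
                        to = unlist(mto)))
}

# ---- one-dimensional stationarity solver -----------------------------------

#' Solve the per-context (or per-position) stationarity equation
#'
#' For a rate multiplier `g` with fixed co-factors, the derivative of the
#' branch likelihood vanishes at the unique root of
#' `sum_i a_i / (1 - exp(-g a_i)) - E = 0`, where `a_i` is the co-factor
#' times branch length at the i-th mutated occurrence and `E` the summed
#' co-factor-times-branch-length exposure over all occurrences. The left
#' side is strictly decreasing in `g`, so the root is unique and found by
#' bracketed search on `[lower, upper]`.
#'
#' @param a_mut numeric vector of `a_i` values (empty if no mutations).
#' @param exposure total exposure `E > 0`.
#' @param lower,upper root brackets.
#' @return list with `value` and `flag` (`"ok"`, `"lower"` or `"upper"`
#'   boundary).
#' @export
solve_rate <- function(a_mut, exposure, lower = 1e-6, upper = 1e3) {
  stopifnot(exposure > 0)
  a_mut <- a_mut[a_mut > 0]
  if (length(a_mut) == 0L)
    return(list(value = lower, flag = "lower"))
  f <- function(g) sum(a_mut / (-expm1(-g * a_mut))) - exposure
  if (f(upper) >= 0) return(list(value = upper, flag = "upper"))
  if (f(lower) <= 0) return(list(value = lower, flag = "lower"))
  r <- uniroot(f, c(lower, upper), tol = 1e-12)
  list(value = r$root, flag = "ok")
}

#' @rdname solve_rate
#' @param beta_t `beta_x * t` at each mutated occurrence of the context.
#' @export
solve_gamma <- function(beta_t, exposure, lower = 1e-6, upper = 1e3)
  solve_rate(beta_t, exposure, lower, upper)

#' @rdname solve_rate
#' @param gamma_t `gamma_w * t` at each mutated occurrence of the position.
#' @export
solve_beta <- function(gamma_t, exposure, lower = 1e-6, upper = 1e3)
  solve_rate(gamma_t, exposure, lower, upper)

# ---- likelihood ------------------------------------------------------------

#' Log-likelihood of one branch under a mutability model
#'
#' Positions whose `gamma` or `beta` is undefined (`NA`) are excluded. Two
#' algebraically identical codings are provided: `"occupancy"` computes
#' `sum_mut log(1 - exp(-mu t)) - sum_unmut mu t` and `"event"` computes
#' `sum_mut log(exp(mu t) - 1) - sum_all mu t`.
#'
#' @param branch an `shm_branch` (see [new_branch()]).
#' @param model a `mutability_model`.
#' @param form which coding to evaluate.
#' @return Log-probability (`-Inf` when a mutation sits on a zero-length
#'   branch).
#' @export
branch_log_likelihood <- function(branch, model,
                                  form = c("occupancy", "event")) {
  form <- match.arg(form)
  p <- branch_positions(branch, model$L)
  mu <- model$gamma[p$w] * model$beta[p$x]
  ok <- !is.na(mu)
  mu <- mu[ok]; mut <- p$mut[ok]
  a <- mu * branch$t
  if (form == "occupancy") {
    sum(log(-expm1(-a[mut]))) - sum(a[!mut])
  } else {
    sum(ifelse(a[mut] > 0, a[mut] + log(-expm1(-a[mut])), -Inf)) - sum(a)
  }
}

total_log_likelihood <- function(stats, gamma, beta) {
  g <- replace(gamma, is.na(gamma), 0)
  b <- replace(beta, is.na(beta), 0)
  a <- gamma[stats$mut$w] * beta[stats$mut$x] * stats$mut$t
  a <- a[!is.na(a)]
  sum(a + log(-expm1(-a))) - drop(g %*% stats$T %*% b)
}

# ---- coordinate-ascent fit -------------------------------------------------

#' Fit the context-and-position mutability model
#'
#' Coordinate-ascent maximum likelihood: all `gamma_w` are updated given
#' `beta` (each by [solve_gamma()]), then all `beta_x` given `gamma`.
#' Iteration stops when the relative change of the total log-likelihood
#' falls below `tol`; the pair is then jointly rescaled so that
#' `mean(beta) = 1` over defined positions (a likelihood-invariant
#' convention that fixes the scale degeneracy of the product
#' `gamma_w beta_x`).
#'
#' Contexts or positions with no exposure are reported `NA` (never
#' imputed); contexts with exposure but no observed mutation sit at the
#' lower solver bracket and are flagged `"lower"`.
#'
#' @param branches list of `shm_branch` objects (see [new_branch()],
#'   [extract_mutation_events()]).
#' @param config an [shm_config()]; `config$L` sets the beta length.
#' @param fit_beta if `FALSE`, `beta` is frozen at 1 (pure context model).
#' @param tol relative log-likelihood convergence tolerance.
#' @param max_iter outer iteration cap.
#' @return A `mutability_model` with extra elements `gamma_flag`,
#'   `beta_flag`, `n_events` and `exposure` per context, `loglik` (trace of
#'   the outer iterations), `converged`.
#' @export
fit_mutability <- function(branches, config = shm_config(), fit_beta = TRUE,
                           tol = 1e-8, max_iter = 100L) {
  L <- config$L
  stats <- branch_stats(branches, L)
  if (nrow(stats$mut) == 0L)
    stop("no mutation events in input branches")
  Tm <- stats$T
  exp_w <- rowSums(Tm)
  obs_w <- which(exp_w > 0)
  obs_x <- which(colSums(Tm) > 0)
  gamma <- rep(NA_real_, 1024L); gamma[obs_w] <- 1
  beta <- rep(NA_real_, L); beta[obs_x] <- 1
  gamma_flag <- rep("unobserved", 1024L)
  beta_flag <- rep("unobserved", L)
  mut_by_w <- split(seq_len(nrow(stats$mut)), factor(stats$mut$w,
                                                     levels = seq_len(1024L)))
  mut_by_x <- split(seq_len(nrow(stats$mut)), factor(stats$mut$x,
                                                     levels = seq_len(L)))
  ll_trace <- numeric(0)
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    b0 <- replace(beta, is.na(beta), 0)
    Ew <- drop(Tm %*% b0)
    for (w in obs_w) {
      i <- mut_by_w[[w]]
      r <- solve_rate(beta[stats$mut$x[i]] * stats$mut$t[i], Ew[w])
      gamma[w] <- r$value; gamma_flag[w] <- r$flag
    }
    if (fit_beta) {
      g0 <- replace(gamma, is.na(gamma), 0)
      Ex <- drop(crossprod(Tm, g0))
      for (x in obs_x) {
        i <- mut_by_x[[x]]
        r <- solve_rate(gamma[stats$mut$w[i]] * stats$mut$t[i], Ex[x])
        beta[x] <- r$value; beta_flag[x] <- r$flag
      }
    }
    ll <- total_log_likelihood(stats, gamma, beta)
    if (it > 1L) {
      prev <- ll_trace[length(ll_trace)]
      if (ll < prev - 1e-6 * abs(prev))
        warning("log-likelihood decreased at iteration ", it)
      if (abs(ll - prev) < tol * abs(prev)) {
        ll_trace <- c(ll_trace, ll)
        converged <- TRUE
        break
      }
    }
    ll_trace <- c(ll_trace, ll)
  }
  # impose the <beta> = 1 convention once, after convergence; rescaling
  # inside the loop would interact with the solver brackets and break the
  # monotonicity of the ascent
  if (fit_beta) {
    sc <- mean(beta, na.rm = TRUE)
    beta <- beta / sc
    gamma <- gamma * sc
  }
  n_events <- tabulate(stats$mut$w, nbins = 1024L)
  model <- mutability_model(gamma, beta)
  model$gamma_flag <- gamma_flag
  model$beta_flag <- beta_flag
  model$n_events <- setNames(n_events, all_fivemers())
  model$exposure <- setNames(exp_w, all_fivemers())
  model$loglik <- ll_trace
  model$converged <- converged
  model
}

# ---- substitution model ----------------------------------------------------

#' Fit the context-conditional substitution model
#'
#' Given fitted targeting rates, the probability that a mutation in context
#' `w` over branch length `t` lands on base `b` is
#' `1 - exp(-gamma_w omega_{w,b} beta_x t)` with
#' `sum_b omega_{w,b} = 1` over the three bases differing from the center
#' of `w`. Per context, `omega` is maximized on the simplex by
#' multiplicative fixed-point updates (`omega_b` proportional to
#' `omega_b * dL/d omega_b`, renormalized), which reduces to the multinomial
#' fraction as `mu t -> 0`.
#'
#' @param branches list of `shm_branch` objects.
#' @param model a fitted `mutability_model`.
#' @return An object of class `substitution_model`: a 1024 x 4 matrix of
#'   `omega` (columns A, C, G, T), `NA` on the center base and for contexts
#'   with no observed mutation.
#' @export
fit_substitution <- function(branches, model, tol = 1e-12, max_iter = 500L) {
  stats <- branch_stats(branches, model$L)
  mut <- stats$mut
  cc <- model$gamma[mut$w] * model$beta[mut$x] * mut$t
  ok <- !is.na(cc) & cc > 0
  mut <- mut[ok, , drop = FALSE]; cc <- cc[ok]
  omega <- matrix(NA_real_, 1024L, 4L,
                  dimnames = list(all_fivemers(), NUC))
  center <- ((seq_len(1024L) - 1L) %/% 16L) %% 4L + 1L
  for (w in unique(mut$w)) {
    i <- which(mut$w == w)
    targets <- setdiff(1:4, center[w])
    counts <- tabulate(match(mut$to[i], targets), nbins = 3L)
    om <- counts / sum(counts)
    ci <- cc[i]
    ti <- match(mut$to[i], targets)
    for (iter in seq_len(max_iter)) {
      grad <- vapply(1:3, function(b) {
        j <- which(ti == b)
        if (!length(j) || om[b] <= 0) return(0)
        sum(ci[j] / (-expm1(-ci[j] * om[b])))
      }, numeric(1))
      new <- om * grad
      s <- sum(new)
      if (s <= 0) break
      new <- new / s
      delta <- max(abs(new - om))
      om <- new
      if (delta < tol) break
    }
    omega[w, targets] <- om
  }
  structure(list(omega = omega), class = "substitution_model")
}

# ---- bootstrap -------------------------------------------------------------

#' Bootstrap confidence intervals for model parameters
#'
#' Resamples the branch list with replacement `B` times, refits, and
#' reports percentile 2.5%/97.5% intervals per parameter.
#'
#' @param branches list of `shm_branch` objects.
#' @param config an [shm_config()]; `config$bootstrap_copies` is the default
#'   `B` and `config$rng_seed` the default seed.
#' @param B number of bootstrap copies.
#' @param seed RNG seed (reproducible intervals).
#' @param ... passed to [fit_mutability()].
#' @return list with the point-estimate `model`, data.frames `gamma_ci`
#'   (fivemer, gamma, ci_low, ci_high, n_events, exposure) and `beta_ci`
#'   (position, beta, ci_low, ci_high), and `B`.
#' @export
bootstrap_ci <- function(branches, config = shm_config(),
                         B = config$bootstrap_copies,
                         seed = config$rng_seed, ...) {
  stopifnot(B >= 2)
  point <- fit_mutability(branches, config, ...)
  set.seed(seed)
  gam <- matrix(NA_real_, B, 1024L)
  bet <- matrix(NA_real_, B, config$L)
  for (b in seq_len(B)) {
    idx <- sample.int(length(branches), replace = TRUE)
    fit <- fit_mutability(branches[idx], config, ...)
    gam[b, ] <- fit$gamma
    bet[b, ] <- fit$beta
  }
  qs <- function(m) apply(m, 2, function(col) {
    if (all(is.na(col))) c(NA_real_, NA_real_)
    else quantile(col, c(0.025, 0.975), na.rm = TRUE, names = FALSE)
  })
  gq <- qs(gam); bq <- qs(bet)
  list(model = point,
       gamma_ci = data.frame(fivemer = all_fivemers(), gamma = point$gamma,
                             ci_low = gq[1, ], ci_high = gq[2, ],
                             n_events = point$n_events,
                             exposure = point$exposure,
                             stringsAsFactors = FALSE),
       beta_ci = data.frame(position = seq_len(config$L) - 1L,
                            beta = point$beta,
                            ci_low = bq[1, ], ci_high = bq[2, ]),
       B = B)
}

# ---- prediction and evaluation ---------------------------------------------

#' Expected per-position mutability profile of a sequence
#'
#' `mu_x = gamma_{w(x)} * beta_x`, `NA` where the 5-mer context is undefined
#' (sequence edges, N) or `x >= L`.
#'
#' @param sequence nucleotide string (at least 5 nt).
#' @param model a `mutability_model`.
#' @return Numeric vector, entry `i` for 0-based position `x = i - 1`.
#' @export
predict_profile <- function(sequence, model) {
  enc <- encode_seq(sequence)
  stopifnot(length(enc) >= 5L)
  ctx <- context_indices(enc)
  x <- seq_along(enc)
  mu <- rep(NA_real_, length(enc))
  ok <- !is.na(ctx) & x <= model$L
  mu[ok] <- model$gamma[ctx[ok]] * model$beta[x[ok]]
  mu
}

#' Squared Pearson correlation between observed and predicted profiles
#'
#' Computed over jointly defined entries. Returns `NA` (with a warning)
#' when fewer than 3 positions are jointly defined or either vector has
#' zero variance.
#'
#' @param observed,predicted equal-length numeric vectors.
#' @return Pearson r-squared, or `NA`.
#' @export
evaluate_r2 <- function(observed, predicted) {
  stopifnot(length(observed) == length(predicted))
  ok <- is.finite(observed) & is.finite(predicted)
  if (sum(ok) < 3L || sd(observed[ok]) == 0 || sd(predicted[ok]) == 0) {
    warning("r-squared undefined (fewer than 3 positions or zero variance)")
    return(NA_real_)
  }
  cor(observed[ok], predicted[ok])^2
}

# ---- parameter table I/O ---------------------------------------------------

#' Write fitted model tables as TSV
#'
#' Writes `gamma.tsv` (fivemer, gamma, n_events, exposure; plus ci columns
#' when a bootstrap result is given), `beta.tsv` (position, beta) and, if a
#' substitution model is supplied, `omega.tsv` (fivemer, to_base, omega).
#'
#' @param model a `mutability_model`, or the result of [bootstrap_ci()].
#' @param dir output directory.
#' @param substitution optional `substitution_model`.
#' @return `dir`, invisibly.
#' @export
write_model <- function(model, dir, substitution = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  if (!is.null(model$model)) {        # bootstrap result
    gdf <- model$gamma_ci
    bdf <- model$beta_ci
  } else {
    gdf <- data.frame(fivemer = all_fivemers(), gamma = model$gamma,
                      n_events = if (is.null(model$n_events)) NA
                                 else model$n_events,
                      exposure = if (is.null(model$exposure)) NA
                                 else model$exposure,
                      stringsAsFactors = FALSE)
    bdf <- data.frame(position = seq_len(model$L) - 1L, beta = model$beta)
  }
  write.table(gdf, file.path(dir, "gamma.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  write.table(bdf, file.path(dir, "beta.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  if (!is.null(substitution)) {
    om <- substitution$omega
    odf <- data.frame(fivemer = rep(rownames(om), 4L),
                      to_base = rep(colnames(om), each = 1024L),
                      omega = as.vector(om), stringsAsFactors = FALSE)
    odf <- odf[order(odf$fivemer, odf$to_base), ]
    write.table(odf, file.path(dir, "omega.tsv"), sep = "\t", quote = FALSE,
                row.names = FALSE)
  }
  invisible(dir)
}

#' Read model tables written by [write_model()]
#' @param dir directory containing `gamma.tsv` and `beta.tsv`.
#' @return A `mutability_model`.
#' @export
read_model <- function(dir) {
  g <- read.delim(file.path(dir, "gamma.tsv"), stringsAsFactors = FALSE)
  b <- read.delim(file.path(dir, "beta.tsv"), stringsAsFactors = FALSE)
  mutability_model(setNames(g$gamma, g$fivemer),
                   b$beta[order(b$position)])
}
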