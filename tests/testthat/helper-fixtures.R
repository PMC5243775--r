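# Shared fixtures, all built in code.

# The printed worked-example individual: 12.2 cm, boldness 1.71,
# activity 1.76, asociability 0.47.
worked_fish <- function() {
  data.frame(fish_id = "worked_example", tl_cm = 12.2,
             boldness = 1.71, activity = 1.76, asociability = 0.47,
             stringsAsFactors = FALSE)
}

# Recording from explicit frame coordinates (px); stimuli point defaults to
# the origin.
make_recording <- function(x_px, y_px, times = NULL, px_per_cm = 1,
                           stimuli = c(0, 0), latency = 100, t_max = 3600,
                           fish_id = "test_fish") {
  if (is.null(times)) times <- 6 * seq_along(x_px)
  assay_recording(
    fish_id = fish_id, latency_s = latency,
    frames = data.frame(time_s = times, x_px = x_px, y_px = y_px),
    px_per_cm = px_per_cm, stimuli_point = stimuli, t_max = t_max
  )
}

# A random-walk recording with known scale; independent of the package's
# generator so it can serve as oracle input.
random_walk_recording <- function(seed, n_frames = 600, px_per_cm = 4,
                                  step_px = 10) {
  set.seed(seed)
  x <- cumsum(c(500, rnorm(n_frames - 1, 0, step_px)))
  y <- cumsum(c(300, rnorm(n_frames - 1, 0, step_px)))
  make_recording(x, y, px_per_cm = px_per_cm, stimuli = c(480, 310))
}

# Random cohort with valid columns for decision-matrix tests.
random_cohort <- function(seed, n = 100) {
  set.seed(seed)
  data.frame(
    fish_id = sprintf("f%03d", seq_len(n)),
    tl_cm = runif(n, 7, 16),
    boldness = runif(n, 0.3, 2),
    activity = runif(n, 0.3, 2),
    asociability = runif(n, 0.2, 1.6),
    stringsAsFactors = FALSE
  )
}

# Design/outcome pair from a known logistic model.
simulate_logit_data <- function(seed, n, beta0 = -0.5, betas = c(1, -0.7)) {
  set.seed(seed)
  x <- matrix(rnorm(n * length(betas)), n, length(betas))
  colnames(x) <- paste0("x", seq_along(betas))
  p <- plogis(beta0 + drop(x %*% betas))
  list(design = x, outcome = rbinom(n, 1, p), p = p)
}

# Independent likelihood maximization (Nelder-Mead on the Bernoulli
# log-likelihood); oracle for the IRLS path.
optim_logit <- function(design, outcome) {
  X <- cbind(1, as.matrix(design))
  nll <- function(b) {
    p <- plogis(drop(X %*% b))
    -sum(outcome * log(pmax(p, 1e-12)) +
           (1 - outcome) * log(pmax(1 - p, 1e-12)))
  }
  fit <- optim(rep(0, ncol(X)), nll, method = "Nelder-Mead",
               control = list(maxit = 50000, reltol = 1e-14))
  fit$par
}
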