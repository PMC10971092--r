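# Shared fixtures: tiny designs, a memoized small fit, and a fake-fit
# constructor for testing assessment operations in isolation.

.cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .cache)) assign(key, expr, envir = .cache)
  get(key, envir = .cache)
}

tiny_design <- function(...) sim_design(I = 12, J = 250, K = 2, ...)

# small but real HO-DINA fit used by several assessment tests
small_hodina_fit <- function() {
  cached("small_fit", {
    dat <- small_dataset()
    fit_dina(dat$y, dat$q, "hodina", iter = 800, burnin = 400, seed = 11)
  })
}

small_dataset <- function() {
  cached("small_data", simulate_dataset(tiny_design(), seed = 42))
}

# minimal dina_fit skeleton with prescribed posterior-mean item parameters
fake_hodina_fit <- function(g, s, q = NULL, profile_counts = NULL) {
  I <- length(g)
  summary <- data.frame(
    parameter = c(paste0("g[", seq_len(I), "]"), paste0("s[", seq_len(I), "]")),
    mean = c(g, s), sd = 0.01, psrf = 1)
  draws <- matrix(rep(c(g, s), each = 2), nrow = 2,
                  dimnames = list(NULL, summary$parameter))
  structure(list(model = "hodina", summary = summary,
                 draws = list(draws, draws), q = q,
                 y_dim = c(if (!is.null(profile_counts))
                   nrow(profile_counts) else 10L, I),
                 profile_counts = profile_counts,
                 features = NULL),
            class = "dina_fit")
}

# independent brute-force DINA log-likelihood: explicit per-cell loop
brute_force_loglik <- function(y, alpha, g, s, q) {
  ll <- 0
  for (j in seq_len(nrow(y))) for (i in seq_len(ncol(y))) {
    eta <- as.integer(all(alpha[j, q[i, ] == 1] == 1))
    p <- if (eta == 1) 1 - s[i] else g[i]
    ll <- ll + log(if (y[j, i] == 1) p else 1 - p)
  }
  ll
}
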