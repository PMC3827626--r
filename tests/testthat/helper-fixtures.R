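# Shared fixtures. Expensive objects (a default synthetic session and its
# cleaned result) are built once per test session and cached.

.fixture_env <- new.env(parent = emptyenv())

cached <- function(name, builder) {
  if (!exists(name, envir = .fixture_env))
    assign(name, builder(), envir = .fixture_env)
  get(name, envir = .fixture_env)
}

default_session <- function() {
  cached("session", function() simulate_session(seed = 1))
}

cleaned_session <- function() {
  cached("cleaned", function() clean_session(default_session()$recording))
}

cleaned_segments <- function() {
  cached("segments", function() {
    sess <- default_session()
    segment_trials(cleaned_session()$rec, trials = sess$paradigm$trials)
  })
}

analysis_inverse <- function() {
  cached("inverse", function() {
    sess <- default_session()
    hm <- sess$head_model
    el <- coregister_electrodes(standard_montage(include_pseudo = TRUE), hm)
    # dense enough that localization blur (~1 mesh edge) stays inside
    # the simulated patches
    src <- source_space(hm, n_per_hemisphere = 300)
    L <- compute_leadfield(hm, src, el)
    ncov <- estimate_noise_cov(cleaned_segments())
    list(inv = build_inverse(L, ncov, snr = 5), src = src, L = L,
         ncov = ncov, el = el)
  })
}

# small artifact-free recording with a known alpha patch, for unit tests
tiny_recording <- function(seed = 3, n_s = 30, fs = 250) {
  with_seed_test(seed, {
    n <- n_s * fs
    labs <- c("O1", "Oz", "O2", "Cz", "Fz")
    data <- matrix(rnorm(length(labs) * n, sd = 2), length(labs))
    data[1:3, ] <- data[1:3, ] +
      matrix(10 * sin(2 * pi * 10 * seq_len(n) / fs), 3, n, byrow = TRUE)
    new_recording(data, labs, fs)
  })
}

# private-seed helper mirroring the package-internal with_seed
with_seed_test <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv())) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  }
  set.seed(seed)
  expr
}

# direction helpers for ground-truth patch geometry
unitize <- function(v) v / sqrt(sum(v^2))
angle_deg <- function(a, b) acos(pmin(pmax(sum(unitize(a) * unitize(b)),
                                           -1), 1)) * 180 / pi
occ_center <- c(0, -1, -0.15)
frontal_center <- c(0, 0.9, 0.45)

# independent connected-component oracle (recursive flood fill, 6-neighbour)
flood_sizes <- function(mask) {
  d <- dim(mask)
  lab <- array(0L, d)
  sizes <- integer()
  nb <- rbind(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0), c(0, -1, 0),
              c(0, 0, 1), c(0, 0, -1))
  cur <- 0L
  for (i in which(mask)) {
    if (lab[i] > 0) next
    cur <- cur + 1L
    stack <- i
    sz <- 0L
    lab[i] <- cur
    while (length(stack) > 0) {
      v <- stack[length(stack)]
      stack <- stack[-length(stack)]
      sz <- sz + 1L
      p <- arrayInd(v, d)
      for (k in 1:6) {
        q <- p + nb[k, ]
        if (any(q < 1) || any(q > d)) next
        j <- q[1] + (q[2] - 1) * d[1] + (q[3] - 1) * d[1] * d[2]
        if (mask[j] && lab[j] == 0) {
          lab[j] <- cur
          stack <- c(stack, j)
        }
      }
    }
    sizes <- c(sizes, sz)
  }
  sizes
}
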