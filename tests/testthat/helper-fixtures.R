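# Shared fixture builders. Everything is generated in code at test time;
# heavyweight phantom pipelines are cached per test run.

# smooth band-limited random field, self-contained (independent of the
# package's own filters so it can serve as neutral test input)
smooth_field <- function(n, sigma = 2, seed = 1, amplitude = 1) {
  set.seed(seed)
  m <- matrix(rnorm(n * n), n, n)
  f <- c(0:floor(n / 2), -(ceiling(n / 2 - 1):1)) / n
  H <- exp(-2 * pi^2 * sigma^2 * outer(f^2, f^2, "+"))
  out <- Re(fft(fft(m) * H, inverse = TRUE)) / n^2
  0.5 + amplitude * out / sd(out) * 0.1
}

# circular integer shift: content of m moved by (dx, dy)
circ_shift <- function(m, dx, dy) {
  n <- nrow(m); p <- ncol(m)
  m[((seq_len(n) - 1 - dy) %% n) + 1, ((seq_len(p) - 1 - dx) %% p) + 1]
}

# small protocol gaze set with exact integer shifts and no jitter; cheap
# enough for unit tests of pair enumeration / canvas assembly
tiny_protocol_sim <- function(seed = 3, px_per_deg = 32) {
  phantom <- make_phantom(n_drusen = 0, n_sdd = 0, n_atrophy = 0,
                          px_per_deg = px_per_deg, seed = seed)
  params <- acquisition_params(fixation_sigma_deg = 0, rotation_range_deg = 0,
                               gain_jitter = 0, offset_jitter = 0,
                               noise_sigma = 0, seed = seed)
  simulate_gaze_set(phantom, params = params)
}

# build a registered stack directly from layer matrices with NA masks
stack_of <- function(...) stack_from_layers(list(...))

# mean intensity over the near/far rim halves of one projected lesion
rim_half_means <- function(img, pl, min_cos = 0.3) {
  w <- nrow(img)
  xs <- rep(0:(w - 1), each = w) - pl$cx_px
  ys <- rep(0:(w - 1), times = w) - pl$cy_px
  r <- sqrt(xs^2 + ys^2)
  phi <- atan2(ys, xs)
  rim <- abs(r - pl$r_peak_px) <= pl$rim_sigma_px
  near <- rim & cos(phi - pl$psi_rad) > min_cos
  far <- rim & cos(phi - pl$psi_rad) < -min_cos
  c(near = mean(img[matrix(near, w, w)]), far = mean(img[matrix(far, w, w)]))
}

# phantom whose lesion table is replaced by explicit rows (kind, position
# in degrees, diameter in micrometers)
phantom_with_lesions <- function(kind, cx_deg, cy_deg, diameter_um,
                                 background = "flat", seed = 1) {
  ph <- make_phantom(n_drusen = 0, n_sdd = 0, n_atrophy = 0,
                     background = background, seed = seed)
  amp <- c(druse = 0.5, sdd = 0.25, atrophy = 0)
  pol <- c(druse = 1, sdd = -1, atrophy = 0)
  ph$lesions <- data.frame(kind = kind, cx_deg = cx_deg, cy_deg = cy_deg,
                           diameter_um = diameter_um,
                           modulation_amplitude = unname(amp[kind]),
                           polarity = unname(pol[kind]),
                           confluent = FALSE, stringsAsFactors = FALSE)
  ph
}

# heavyweight fixtures, computed once per test session
.fixture_cache <- new.env(parent = emptyenv())

cached <- function(name, build) {
  if (!exists(name, envir = .fixture_cache)) {
    assign(name, build(), envir = .fixture_cache)
  }
  get(name, envir = .fixture_cache)
}

default_phantom_run <- function() {
  cached("default_run", function() {
    phantom <- make_phantom(seed = 11)
    sim <- simulate_gaze_set(phantom, params = acquisition_params(seed = 11))
    pipe <- gaze_pipeline(sim$set, radius_px = 5)
    list(phantom = phantom, sim = sim, pipe = pipe,
         proj = project_lesions(sim$truth, pipe$stack))
  })
}
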