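# Shared, lazily built fixtures (cached across test files to keep the suite
# fast) and small independent oracles.

.fixtures <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .fixtures))
    assign(key, force(expr), envir = .fixtures)
  get(key, envir = .fixtures)
}

# one 600-s stochastic trajectory + its kinematic products
shared_kin <- function() {
  cached("kin600", {
    traj <- simulate_trajectory(600, seed = 42)
    pos <- interpolate_position(traj, duration = 600)
    xs <- smooth_position(pos$x); ys <- smooth_position(pos$y)
    list(traj = traj, x = xs, y = ys, speed = compute_speed(xs, ys),
         duration = 600)
  })
}

# von Mises sampler (Best & Fisher 1979 rejection method) -- an independent
# oracle for circular statistics, not the package's spike path
rvonmises <- function(n, mu, kappa) {
  if (kappa == 0) return(runif(n, 0, 2 * pi))
  a <- 1 + sqrt(1 + 4 * kappa^2)
  b <- (a - sqrt(2 * a)) / (2 * kappa)
  r <- (1 + b^2) / (2 * b)
  out <- numeric(n); i <- 0L
  while (i < n) {
    u1 <- runif(1); u2 <- runif(1); u3 <- runif(1)
    z <- cos(pi * u1)
    f <- (1 + r * z) / (r + z)
    c0 <- kappa * (r - f)
    if (c0 * (2 - c0) - u2 > 0 || log(c0 / u2) + 1 - c0 >= 0) {
      i <- i + 1L
      out[i] <- (mu + sign(u3 - 0.5) * acos(f)) %% (2 * pi)
    }
  }
  out
}

# analytic rate-map matrix on the package's bin grid
analytic_map <- function(f, side = 120, bin = 3) {
  n <- as.integer(side / bin)
  xc <- (seq_len(n) - 0.5) * bin
  outer(xc, xc, f)
}

hex_map <- function(spacing = 40, side = 120, bin = 3)
  analytic_map(function(x, y) {
    k <- 4 * pi / (sqrt(3) * spacing)
    ang <- c(0, pi / 3, 2 * pi / 3)
    Reduce(`+`, lapply(ang, function(a)
      cos(k * (x * cos(a) + y * sin(a))))) + 1.5
  }, side, bin)
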