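## Independent oracles and fixture builders shared across test files.
## Oracles are deliberately written as naive loops, separate from the
## package's implementation paths.

## Brute-force 1-D TFCE: explicit double loop over thresholds and a literal
## connected-run search at each threshold.
tfce_oracle <- function(z, E = 0.5, H = 2, dh = 0.01, two_sided = TRUE) {
  one <- function(z) {
    m <- length(z)
    out <- numeric(m)
    if (max(z) <= 0) return(out)
    nsteps <- ceiling(max(z) / dh - 1e-12)
    for (i in seq_len(nsteps)) {
      h <- i * dh
      above <- z >= h
      for (j in seq_len(m)) {
        if (!above[j]) next
        lo <- j
        while (lo > 1 && above[lo - 1]) lo <- lo - 1
        hi <- j
        while (hi < m && above[hi + 1]) hi <- hi + 1
        out[j] <- out[j] + (hi - lo + 1)^E * h^H * dh
      }
    }
    out
  }
  if (two_sided) one(z) + one(-z) else one(z)
}

## Exhaustive Mann-Whitney: permutation distribution of U over all
## assignments of m of the pooled values to group a; two-sided p by
## symmetric tail |U - mn/2|.
mw_enum_oracle <- function(a, b) {
  m <- length(a); n <- length(b)
  pool <- c(a, b)
  U_of <- function(idx) {
    r <- rank(pool)
    sum(r[idx]) - m * (m + 1) / 2
  }
  U_obs <- U_of(seq_len(m))
  combos <- utils::combn(m + n, m)
  U_all <- apply(combos, 2L, U_of)
  mu <- m * n / 2
  list(U = U_obs, p = mean(abs(U_all - mu) >= abs(U_obs - mu) - 1e-9))
}

## Exhaustive Barnard oracle: same sampling model, independently coded
## (dbinom products, dense nuisance grid).
barnard_oracle <- function(tb, grid_step = 0.001) {
  c1 <- sum(tb[, 1]); c2 <- sum(tb[, 2])
  stat <- function(a, b) {
    ph <- (a + b) / (c1 + c2)
    den <- sqrt(ph * (1 - ph) * (1 / c1 + 1 / c2))
    if (!is.finite(den) || den == 0) return(0)
    (a / c1 - b / c2) / den
  }
  t_obs <- stat(tb[1, 1], tb[1, 2])
  pis <- seq(grid_step, 1 - grid_step, by = grid_step)
  best <- 0
  for (pi0 in pis) {
    tot <- 0
    for (a in 0:c1) for (b in 0:c2) {
      if (abs(stat(a, b)) >= abs(t_obs) - 1e-12) {
        tot <- tot + dbinom(a, c1, pi0) * dbinom(b, c2, pi0)
      }
    }
    if (tot > best) best <- tot
  }
  min(best, 1)
}

## Simple parametric curves for geometry tests.
helix_streamline <- function(n = 50, turns = 0.6, r = 12, pitch = 18) {
  th <- seq(0, turns * 2 * pi, length.out = n)
  streamline(cbind(r * cos(th), r * sin(th), pitch * th / (2 * pi) + 0.3 * th^2))
}

circle_streamline <- function(n = 50, r = 10, span = 2 * pi * 0.999) {
  th <- seq(0, span, length.out = n)
  streamline(cbind(r * cos(th), r * sin(th), 0))
}

rot_z <- function(deg) {
  a <- deg * pi / 180
  matrix(c(cos(a), -sin(a), 0, sin(a), cos(a), 0, 0, 0, 1), 3, 3, byrow = TRUE)
}

## Small aligned multi-subject arc set ready for joint parameterization.
aligned_arc_bundles <- function(spec, n_left = 3, n_right = 3,
                                seed_base = 100) {
  ms <- tractcrowd:::map_streamlines
  bs <- list()
  for (i in seq_len(n_left))
    bs[[length(bs) + 1L]] <- make_arc_bundle(spec, "left",
                                             subject_id = sprintf("L%d", i),
                                             seed = seed_base + i)
  for (i in seq_len(n_right))
    bs[[length(bs) + 1L]] <- mirror_bundle(
      make_arc_bundle(spec, "right", subject_id = sprintf("R%d", i),
                      seed = seed_base + 50 + i))
  bs <- lapply(bs, function(b)
    harmonize_orientation(ms(b, function(s) unclass(resample_streamline(s, 50)))))
  reps <- lapply(bs, representative_streamline)
  for (i in seq_along(bs))
    bs[[i]] <- apply_rigid(icp_align(reps[[i]], reps[[1]]), bs[[i]])
  bs
}

## Minimal valid subject table as a data.frame.
subjects_fixture <- function() {
  data.frame(
    subject_id = c("p1", "p2", "c1", "c2"),
    group = c("patient", "patient", "control", "control"),
    contralesional_hemisphere = c("left", "right", "n/a", "n/a"),
    etiology = c("congenital", "acquired", "n/a", "n/a"),
    viq = c(85.5, 71.5, 102, 98),
    piq = c(64.5, 73.5, 101, 97),
    age_at_scan = c(20.4, 25.1, 23.8, 30.2),
    age_at_surgery = c(12.15, 10.2, NA, NA),
    age_at_onset = c(3.5, 2.0, NA, NA),
    skeleton_mean_fa = c(0.41, 0.39, 0.40, 0.42),
    stringsAsFactors = FALSE)
}
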