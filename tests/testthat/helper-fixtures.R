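# Shared fixtures and independent oracles for the test suite.

# A well-conditioned, clearly non-trivial mixing matrix for recovery tests.
known_mixing <- function() {
  rbind(c(0.85, 0.10, 0.05),
        c(0.08, 0.84, 0.08),
        c(0.04, 0.12, 0.84))
}

known_profile <- function(camera_id = "known", lighting_id = "L", ...) {
  camera_profile(camera_id = camera_id, lighting_id = lighting_id,
                 mixing_matrix = known_mixing(), ...)
}

# Independent per-pixel loop oracle for the four redness metrics: explicit
# scalar arithmetic, no shared code with score_redness().
loop_score <- function(px, mask, red_lo = 330, red_hi = 30,
                       chroma_floor = 0.01, sat = 0.99) {
  h <- dim(px)[1]; w <- dim(px)[2]
  rel <- 0; rg <- 0; rb <- 0; red <- 0; n <- 0
  for (i in seq_len(h)) {
    for (j in seq_len(w)) {
      if (!mask[i, j]) next
      r <- px[i, j, 1]; g <- px[i, j, 2]; b <- px[i, j, 3]
      if (r >= sat || g >= sat || b >= sat) next
      n <- n + 1
      s <- r + g + b
      if (s > 0) rel <- rel + r / s
      rg <- rg + (r - g)
      rb <- rb + (r - b)
      mx <- max(r, g, b); mn <- min(r, g, b); ch <- mx - mn
      if (ch >= chroma_floor) {
        hdeg <- if (mx == r) 60 * (((g - b) / ch) %% 6)
        else if (mx == g) 60 * ((b - r) / ch + 2)
        else 60 * ((r - g) / ch + 4)
        hdeg <- hdeg %% 360
        inband <- if (red_lo > red_hi) (hdeg >= red_lo || hdeg <= red_hi)
        else (hdeg >= red_lo && hdeg <= red_hi)
        if (inband) red <- red + 1
      }
    }
  }
  list(relative_redness = rel, rg_diff = rg / n, rb_diff = rb / n,
       red_hue = red / n, n_pixels = n)
}

# Brute-force cell-mean oracle for the balanced within-subjects ANOVA:
# inclusion-exclusion over explicit data subsets, nothing shared with
# rm_anova()'s array machinery.
brute_ss <- function(d, response, term_cols) {
  y <- d[[response]]
  grand <- mean(y)
  combos <- unique(d[term_cols])
  ss <- 0
  for (r in seq_len(nrow(combos))) {
    sel <- rep(TRUE, nrow(d))
    for (cl in term_cols) sel <- sel & d[[cl]] == combos[[cl]][r]
    delta <- 0
    k <- length(term_cols)
    for (m in 0:k) {
      for (sub in if (m == 0) list(character(0)) else
           utils::combn(term_cols, m, simplify = FALSE)) {
        sel_u <- rep(TRUE, nrow(d))
        for (cl in sub) sel_u <- sel_u & d[[cl]] == combos[[cl]][r]
        delta <- delta + (-1)^(k - m) * mean(y[sel_u])
      }
    }
    ss <- ss + sum(sel) * delta^2
  }
  ss
}

brute_rm_anova <- function(d, response, factors, subject = "subject") {
  effects <- unlist(lapply(seq_along(factors), function(k)
    utils::combn(factors, k, simplify = FALSE)), recursive = FALSE)
  do.call(rbind, lapply(effects, function(E) {
    data.frame(effect = paste(E, collapse = ":"),
               ss = brute_ss(d, response, E),
               error_ss = brute_ss(d, response, c(subject, E)))
  }))
}

# Small helper: a quick two-subject design for pipeline tests.
small_design <- function(seed = 11L, image_size = 64L) {
  study_design(subjects = c("S1", "S2"), image_size = image_size, seed = seed)
}
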