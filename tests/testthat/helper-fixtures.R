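# shared fixtures, built in code

log1mexp_pkg <- function(a) jointGIED:::log1mexp(a)

# tiny worked sample: m = n = 2, one withdrawal per line
toy_sample <- function() {
  jpc_sample(w = c(1, 2), z = c(1, 0), s = c(1, 0), t = c(0, 1),
             scheme = jpc_scheme(2, 2, 2, c(1, 1)))
}

# small scheme for quick simulation-based tests
small_scheme <- function() jpc_scheme(10, 10, 12, c(rep(0L, 11), 8L))

# deterministic k = 4 sample with a bounded profile likelihood (interior MLE).
# The 2-failure toy sample is kept for closed-form checks only: with k = 2 and
# one failure per line, k1/w1 + k2/w2 equals sum(1/w_i) exactly, the lambda
# coefficients of the profile log-likelihood cancel, and p1 grows like
# k log(lambda) without a finite maximizer.
demo_sample <- function() {
  jpc_sample(w = c(0.5, 1, 1.5, 2.5), z = c(1, 0, 1, 0),
             s = c(1, 0, 0, 0), t = c(0, 0, 1, 0),
             scheme = jpc_scheme(3, 3, 4, c(1, 0, 1, 0)))
}

# the m = 20, n = 25 simulation-study schemes (k = 20, 25, 30)
study_schemes <- function(k = c(20L, 25L, 30L)) {
  all <- list(
    `20` = c("(0(4),25,0(15))", "(0(9),25,0(10))", "(0(14),25,0(5))",
             "(0(5),5(5),0(10))", "(25,0(19))", "(2(12),1,0(7))"),
    # the k = 25 row of the published table misprints its last two schemes
    # ((20,0(14)) and (2(10),1,0(15)) fail sum(R+1) = 45); the corrected
    # entries below follow the row's evident pattern
    `25` = c("(0(4),20,0(20))", "(0(9),20,0(15))", "(0(14),20,0(10))",
             "(0(5),5(4),0(16))", "(20,0(24))", "(2(10),0(15))"),
    # k = 30: the published "(0(5),5(6),0(19))" gives sum(R+1) = 60, not 45;
    # 5(3) restores the accounting
    `30` = c("(0(4),15,0(25))", "(0(9),15,0(20))", "(0(14),15,0(15))",
             "(0(5),5(3),0(22))", "(15,0(29))", "(2(7),1,0(22))"))
  out <- list()
  for (kk in as.character(k)) {
    out <- c(out, lapply(all[[kk]], function(nt)
      jpc_scheme(20, 25, as.integer(kk), nt)))
  }
  out
}

# draw a JPC sample guaranteed to have failures on both lines
draw_valid_jpc <- function(scheme, theta1, theta2, lambda) {
  repeat {
    d <- rjpc(scheme, theta1, theta2, lambda)
    if (d$k1 > 0 && d$k2 > 0) return(d)
  }
}

jute10 <- function() {
  j <- jute_fiber()
  j$strength[j$gauge == "10mm"]
}
jute20 <- function() {
  j <- jute_fiber()
  j$strength[j$gauge == "20mm"]
}
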