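#' Finite-difference validation of margin-loss gradients
#'
#' Builds a random embedding state and a random batch of positive and
#' corrupted triplets, then compares the analytic gradient of the
#' margin-ranking loss against central finite differences, coordinate by
#' coordinate, for the chosen mapping variant and metric.  Because the L1
#' metric is non-smooth, batches whose residual coordinates or hinge
#' activations fall within `100 * eps` of a kink are redrawn.
#'
#' @param variant mapping variant (see [kge_fit()]).
#' @param norm `"L1"` or `"L2"`.
#' @param dim embedding dimension of the random state.
#' @param n_ent,n_rel,n_pairs size of the random state and batch.
#' @param margin ranking margin of the evaluated loss.
#' @param eps central-difference step.
#' @param seed RNG seed.
#' @return Maximum relative error `|analytic - numeric| / max(1, |.|)`
#'   over all parameter coordinates the variant uses.
#' @export
check_gradients <- function(variant = c("dynmap", "nomap", "planemap",
                                        "staticmap"),
                            norm = c("L1", "L2"), dim = 6L, n_ent = 8L,
                            n_rel = 3L, n_pairs = 5L, margin = 1,
                            eps = 1e-5, seed = 1L) {
  variant <- match.arg(variant)
  norm <- match.arg(norm)
  vc <- variant_code(variant)
  nc <- norm_code(norm)
  set.seed(as.integer(seed))

  draw_state <- function() {
    list(E = matrix(runif(n_ent * dim, -0.9, 0.9), n_ent, dim),
         P = matrix(runif(n_ent * dim, -0.6, 0.6), n_ent, dim),
         R = matrix(runif(n_rel * dim, -0.9, 0.9), n_rel, dim),
         Q = matrix(runif(n_rel * dim, -0.9, 0.9), n_rel, dim),
         M = matrix(runif(n_rel * dim * dim, -0.7, 0.7), n_rel, dim * dim),
         ph = sample.int(n_ent, n_pairs, TRUE) - 1L,
         pr = sample.int(n_rel, n_pairs, TRUE) - 1L,
         pt = sample.int(n_ent, n_pairs, TRUE) - 1L,
         nh = sample.int(n_ent, n_pairs, TRUE) - 1L,
         nt = sample.int(n_ent, n_pairs, TRUE) - 1L)
  }
  loss_of <- function(s) {
    cpp_batch_loss_grad(s$E, s$P, s$R, s$Q, s$M, s$ph, s$pr, s$pt,
                        s$nh, s$pr, s$nt, margin, vc, nc, FALSE)$loss
  }
  away_from_kinks <- function(s) {
    res <- function(h, r, t) {
      sc1 <- cpp_score_triplets(s$E, s$P, s$R, s$Q, s$M, h, r, t, vc, 1L)
      sc2 <- cpp_score_triplets(s$E, s$P, s$R, s$Q, s$M, h, r, t, vc, nc)
      list(l1 = sc1, s = sc2)
    }
    p <- res(s$ph, s$pr, s$pt); n <- res(s$nh, s$pr, s$nt)
    hinges <- margin + p$s - n$s
    # residual coordinates near 0 would flip sign inside the FD stencil;
    # an L1 score is the sum of |coords|, so probe coordinate-wise below
    ok <- all(abs(hinges) > 100 * eps)
    if (ok && nc == 1L) {
      probe <- function(h, r, t) {
        e <- vapply(seq_along(h), function(i) {
          ei <- residual_coords(s, h[i], r[i], t[i], vc)
          min(abs(ei))
        }, numeric(1))
        all(e > 100 * eps)
      }
      ok <- probe(s$ph, s$pr, s$pt) && probe(s$nh, s$pr, s$nt)
    }
    ok
  }
  s <- draw_state()
  tries <- 0L
  while (!away_from_kinks(s) && tries < 50L) {
    s <- draw_state(); tries <- tries + 1L
  }

  an <- cpp_batch_loss_grad(s$E, s$P, s$R, s$Q, s$M, s$ph, s$pr, s$pt,
                            s$nh, s$pr, s$nt, margin, vc, nc, TRUE)
  used <- switch(variant,
                 nomap = c("E", "R"),
                 planemap = c("E", "R", "Q"),
                 staticmap = c("E", "R", "M"),
                 dynmap = c("E", "P", "R", "Q"))
  max_err <- 0
  for (nm in used) {
    g_an <- an[[paste0("g", nm)]]
    x <- s[[nm]]
    for (i in seq_along(x)) {
      s2 <- s
      s2[[nm]][i] <- x[i] + eps
      up <- loss_of(s2)
      s2[[nm]][i] <- x[i] - eps
      dn <- loss_of(s2)
      fd <- (up - dn) / (2 * eps)
      err <- abs(g_an[i] - fd) / max(1, abs(g_an[i]), abs(fd))
      max_err <- max(max_err, err)
    }
  }
  max_err
}

# residual vector of one triplet, recomputed in R (diagnostic use)
residual_coords <- function(s, h, r, t, vc) {
  d <- ncol(s$E)
  vh <- s$E[h + 1L, ]; vt <- s$E[t + 1L, ]; vr <- s$R[r + 1L, ]
  if (vc == 0L) return(vh + vr - vt)
  if (vc == 1L) {
    w <- s$Q[r + 1L, ]
    return((vh - sum(w * vh) * w) + vr - (vt - sum(w * vt) * w))
  }
  if (vc == 2L) {
    M <- matrix(s$M[r + 1L, ], d, d)
    return(as.numeric(M %*% vh) + vr - as.numeric(M %*% vt))
  }
  w <- s$Q[r + 1L, ]
  (vh + w * sum(s$P[h + 1L, ] * vh)) + vr -
    (vt + w * sum(s$P[t + 1L, ] * vt))
}
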