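# Independent reference implementations used as oracles. Each is written
# from the definition, with no code shared with the package internals.

# Exhaustive optimal 1-D k-means: tries every interval 4-partition of the
# sorted values (the 1-D optimum is always an interval partition).
oracle_kmeans1d_wcss <- function(x, k = 4) {
  xs <- sort(x)
  n <- length(xs)
  cs <- c(0, cumsum(xs))
  cs2 <- c(0, cumsum(xs^2))
  seg_cost <- function(i, j) {  # xs[i..j]
    s <- cs[j + 1] - cs[i]
    (cs2[j + 1] - cs2[i]) - s^2 / (j - i + 1)
  }
  cuts <- utils::combn(n - 1, k - 1)
  best <- Inf
  for (c_i in seq_len(ncol(cuts))) {
    b <- c(0, cuts[, c_i], n)
    w <- 0
    for (m in seq_len(k)) w <- w + seg_cost(b[m] + 1, b[m + 1])
    if (w < best) best <- w
  }
  best
}

# Absorb-until-fixpoint smoothing on (role, duration) runs, list-based.
oracle_smooth <- function(role, dur, min_s) {
  merge_adj <- function(role, dur) {
    out_r <- character(0); out_d <- numeric(0)
    for (i in seq_along(role)) {
      if (length(out_r) > 0 && out_r[length(out_r)] == role[i]) {
        out_d[length(out_d)] <- out_d[length(out_d)] + dur[i]
      } else {
        out_r <- c(out_r, role[i]); out_d <- c(out_d, dur[i])
      }
    }
    list(role = out_r, dur = out_d)
  }
  st <- merge_adj(role, dur)
  repeat {
    n <- length(st$role)
    if (n <= 1) break
    is_short <- st$dur < min_s
    if (!any(is_short)) break
    i <- which(is_short & st$dur == min(st$dur[is_short]))[1]
    j <- if (i == 1) 2 else if (i == n) n - 1
         else if (st$dur[i - 1] >= st$dur[i + 1]) i - 1 else i + 1
    st$role[i] <- st$role[j]
    st <- merge_adj(st$role, st$dur)
  }
  st
}

# REML criterion for the random-intercept model, profiled over sigma^2 and
# maximized over the variance ratio by generic 1-D optimization.
oracle_reml_fit <- function(y, X, group) {
  n <- length(y)
  p <- ncol(X)
  Z <- stats::model.matrix(~ 0 + factor(group))
  neg2_reml <- function(log_lambda) {
    V <- diag(n) + exp(log_lambda) * tcrossprod(Z)
    Vi <- solve(V)
    XtVi <- crossprod(X, Vi)
    A <- XtVi %*% X
    beta <- solve(A, XtVi %*% y)
    r <- y - X %*% beta
    s2 <- drop(crossprod(r, Vi %*% r)) / (n - p)
    (n - p) * log(s2) + determinant(V)$modulus +
      determinant(A)$modulus + (n - p)
  }
  opt <- stats::optimize(neg2_reml, c(-10, 10))
  lambda <- exp(opt$minimum)
  V <- diag(n) + lambda * tcrossprod(Z)
  Vi <- solve(V)
  XtVi <- crossprod(X, Vi)
  beta <- solve(XtVi %*% X, XtVi %*% y)
  r <- y - X %*% beta
  s2 <- drop(crossprod(r, Vi %*% r)) / (n - p)
  list(beta = drop(beta), sigma2 = s2, tau2 = lambda * s2)
}

# small helper: a plain segment tibble
seg_tbl <- function(dur, role) {
  end <- cumsum(dur)
  tibble::tibble(start_s = c(0, end[-length(end)]), end_s = end, role = role)
}

# quick config for short synthetic conversations (keeps frame counts small)
small_config <- function(...) {
  args <- utils::modifyList(
    list(n_participants = 3,
         conversations_per_participant = list(mean = 4, sd = 1, min = 3,
                                              max = 5),
         length_s = list(mean = 90, sd = 30, min = 45, max = 180)),
    list(...))
  do.call(generator_config, args)
}
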