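# Structural identifiability and observability (SIO) analysis.
#
# The observability-identifiability matrix stacks gradients (with respect to
# the augmented state x~ = (x, p)) of iterated Lie derivatives of the outputs.
# A model is FISPO when this matrix has full generic rank n + np.
#
# Two routes are provided:
#  * lie_derivative_rows(): fully symbolic rows via exact rational-function
#    arithmetic (transparent, used for small models and in tests);
#  * the rank engine used by classify(): exact arithmetic modulo a prime at
#    random integer specializations. Rather than expanding Lie derivatives
#    symbolically, it propagates a truncated power series of the augmented
#    trajectory z(t) together with its sensitivity S(t) = dz(t)/dz(0); the
#    i-th block of OI rows at the specialization point equals
#    i! * [t^i] (dg/dx~(z(t)) %*% S(t)), because the gradient of the i-th
#    output derivative with respect to the initial augmented state is exactly
#    the gradient of the i-th Lie derivative. This keeps the Glycolysis-scale
#    analyses (36 augmented states) to fractions of a second while remaining
#    float-free.

SIO_PRIME <- 2097143  # < 2^21, so products of residues are exact in doubles

# ---- power series over F_p -------------------------------------------------

ser_const <- function(v, K, p) c(v %% p, rep(0, K))
ser_add <- function(a, b, p) (a + b) %% p
ser_sub <- function(a, b, p) (a - b) %% p
ser_mul <- function(a, b, p) {
  K <- length(a) - 1
  out <- numeric(K + 1)
  for (k in 0:K)
    out[k + 1] <- sum(a[1:(k + 1)] * b[(k + 1):1]) %% p
  out
}
ser_div <- function(a, b, p) {
  if (b[1] %% p == 0) stop("series division by series with zero constant term")
  K <- length(a) - 1
  inv0 <- .mod_inv(b[1], p)
  cs <- numeric(K + 1)
  for (k in 0:K) {
    acc <- a[k + 1]
    if (k > 0) acc <- acc - sum(cs[1:k] * b[(k + 1):2])
    cs[k + 1] <- (acc %% p * inv0) %% p
  }
  cs %% p
}
ser_pow <- function(a, n, p) {
  K <- length(a) - 1
  out <- ser_const(1, K, p)
  base <- a; n <- as.integer(n)
  while (n > 0) {
    if (n %% 2L == 1L) out <- ser_mul(out, base, p)
    base <- ser_mul(base, base, p)
    n <- n %/% 2L
  }
  out
}

.num_mod <- function(x, p) {
  q <- .as_rat(x)
  (q[1] %% p * .mod_inv(q[2] %% p, p)) %% p
}

# evaluate an R expression over series arguments (env: name -> series)
ser_eval <- function(e, env, K, p) {
  if (is.numeric(e)) return(ser_const(.num_mod(as.numeric(e), p), K, p))
  if (is.symbol(e)) {
    v <- env[[as.character(e)]]
    if (is.null(v)) stop("unbound symbol in series evaluation: ", e)
    return(v)
  }
  op <- as.character(e[[1]])
  if (op == "(") return(ser_eval(e[[2]], env, K, p))
  if (op == "+" && length(e) == 2) return(ser_eval(e[[2]], env, K, p))
  if (op == "-" && length(e) == 2)
    return((p - ser_eval(e[[2]], env, K, p)) %% p)
  a <- ser_eval(e[[2]], env, K, p)
  if (op == "^") return(ser_pow(a, as.numeric(e[[3]]), p))
  b <- ser_eval(e[[3]], env, K, p)
  switch(op,
         "+" = ser_add(a, b, p),
         "-" = ser_sub(a, b, p),
         "*" = ser_mul(a, b, p),
         "/" = ser_div(a, b, p),
         stop("unsupported operation in series evaluation: ", op))
}

# rank of a matrix over F_p by Gaussian elimination
rank_mod <- function(M, p) {
  M <- M %% p
  r <- 0
  nr <- nrow(M); nc <- ncol(M)
  for (j in seq_len(nc)) {
    piv <- which(M[r + seq_len(nr - r), j] != 0)
    if (!length(piv)) next
    i <- r + piv[1]
    if (i != r + 1) M[c(r + 1, i), ] <- M[c(i, r + 1), ]
    M[r + 1, ] <- (M[r + 1, ] * .mod_inv(M[r + 1, j], p)) %% p
    below <- which(M[, j] != 0)
    below <- below[below != r + 1]
    for (i2 in below) M[i2, ] <- (M[i2, ] - M[i2, j] * M[r + 1, ]) %% p
    r <- r + 1
    if (r == nr) break
  }
  r
}

# ---- OI row blocks at one specialization ----------------------------------

# returns rows (one block per order 0..K-1) of the OI matrix at a random
# integer point, or NULL if the point hits a singularity
.oi_blocks_at_point <- function(aug, point, K, p, known_vals) {
  nxt <- aug$nxt
  vars <- aug$states
  penv0 <- list()
  for (nm in names(known_vals)) penv0[[nm]] <- ser_const(.num_mod(known_vals[[nm]], p), K, p)
  # augmented trajectory series
  z <- lapply(seq_len(nxt), function(i) {
    s <- ser_const(point[i] %% p, K, p)
    s
  })
  names(z) <- vars
  env_of <- function(z) c(z, penv0)
  ok <- TRUE
  F <- NULL
  for (k in 0:(K - 1)) {
    F <- tryCatch(lapply(aug$dynamics, ser_eval, env = env_of(z), K = K, p = p),
                  error = function(e) NULL)
    if (is.null(F)) return(NULL)
    inv <- .mod_inv((k + 1) %% p, p)
    for (i in seq_len(nxt)) z[[i]][k + 2] <- (F[[i]][k + 1] * inv) %% p
  }
  # Jacobian series J[i,j](z)
  Jx <- array(0, dim = c(nxt, nxt, K + 1))
  for (i in seq_len(nxt)) {
    ei <- aug$dynamics[[i]]
    if (identical(ei, quote(0)) || identical(ei, 0)) next
    sv <- all.vars(ei)
    for (j in seq_len(nxt)) {
      if (!(vars[j] %in% sv)) next
      de <- stats::D(ei, vars[j])
      val <- tryCatch(ser_eval(de, env_of(z), K, p), error = function(e) NULL)
      if (is.null(val)) return(NULL)
      Jx[i, j, ] <- val
    }
  }
  # sensitivity series: S' = J(z) S, S(0) = I
  S <- array(0, dim = c(nxt, nxt, K + 1))
  S[, , 1] <- diag(nxt)
  for (k in 0:(K - 1)) {
    M <- matrix(0, nxt, nxt)
    for (a in 0:k) M <- M + Jx[, , a + 1] %*% S[, , k - a + 1] %% p
    inv <- .mod_inv((k + 1) %% p, p)
    S[, , k + 2] <- ((M %% p) * inv) %% p
  }
  # output gradient series w_j(t) and row blocks
  fact <- 1
  blocks <- vector("list", K)
  grads <- lapply(aug$outputs, function(g) {
    sv <- all.vars(g)
    lapply(seq_len(nxt), function(j) {
      if (!(vars[j] %in% sv)) return(ser_const(0, K, p))
      val <- ser_eval(stats::D(g, vars[j]), env_of(z), K, p)
      val
    })
  })
  # w.S per output: series row vector
  WS <- lapply(grads, function(w) {
    out <- matrix(0, nxt, K + 1)
    for (k in 0:K) {
      v <- numeric(nxt)
      for (a in 0:k) {
        wa <- vapply(w, function(s) s[a + 1], numeric(1))
        v <- v + (wa %*% S[, , k - a + 1])[1, ] %% p
      }
      out[, k + 1] <- v %% p
    }
    out
  })
  for (ord in 0:(K - 1)) {
    if (ord > 0) fact <- (fact * ord) %% p
    blocks[[ord + 1]] <- do.call(rbind, lapply(WS, function(M)
      (M[, ord + 1] * fact) %% p))
  }
  blocks
}

.sample_point <- function(nxt) sample(2:97, nxt, replace = TRUE)

# core rank computation with early stopping: returns list(rank, order, rows,
# point) for one specialization
.oi_rank_one <- function(aug, K0 = NULL, p = SIO_PRIME, max_attempts = 25) {
  nxt <- aug$nxt
  known_vals <- aug$known_values %||% numeric()
  Kmax <- nxt  # orders 0..nxt-1
  K <- min(if (is.null(K0)) max(4, min(12, Kmax)) else K0, Kmax)
  for (att in seq_len(max_attempts)) {
    point <- .sample_point(nxt)
    blocks <- .oi_blocks_at_point(aug, point, K, p, known_vals)
    if (is.null(blocks)) next
    repeat {
      rows <- NULL; ranks <- integer(0)
      done <- FALSE
      for (ord in seq_along(blocks)) {
        rows <- rbind(rows, blocks[[ord]])
        r <- rank_mod(rows, p)
        ranks <- c(ranks, r)
        n_ord <- length(ranks)
        if (r == nxt ||
            (n_ord >= 3 && ranks[n_ord] == ranks[n_ord - 1] &&
             ranks[n_ord - 1] == ranks[n_ord - 2]) ||
            n_ord == Kmax) {
          done <- TRUE
          break
        }
      }
      if (done) return(list(rank = ranks[length(ranks)],
                            order = length(ranks) - 1L,
                            rows = rows, point = point))
      # extend the series and continue
      K <- min(K * 2, Kmax)
      blocks <- .oi_blocks_at_point(aug, point, K, p, known_vals)
      if (is.null(blocks)) break
    }
  }
  stop("could not find a nonsingular specialization point")
}

#' Generic rank of the observability-identifiability matrix
#'
#' Computes the generic rank by exact modular arithmetic at random integer
#' specializations of the augmented state (range 2..97, resampled if a
#' denominator vanishes), taking the maximum over `n_trials` draws.
#'
#' @param model an [ode_model] (or an `oi_matrix` from
#'   [lie_derivative_rows()]).
#' @param n_trials number of random specializations (default 3).
#' @param seed integer seed making the specialization points reproducible.
#' @return the generic rank (integer).
#' @export
generic_rank <- function(model, n_trials = 3, seed = 1) {
  set.seed(seed)
  if (inherits(model, "oi_matrix")) return(oi_matrix_rank(model, n_trials))
  aug <- augment(model)
  max(vapply(seq_len(n_trials), function(i) .oi_rank_one(aug)$rank, numeric(1)))
}

#' Classify structural identifiability and observability
#'
#' Builds the observability-identifiability matrix with increasing
#' Lie-derivative order until the generic rank is stable over two consecutive
#' orders (or full rank / the theoretical order bound is reached). The model
#' is FISPO iff the rank equals the augmented dimension. Individual
#' parameters (and states) are classified by a column-deletion test: a
#' variable is structurally unidentifiable (unobservable) iff removing its
#' column leaves the generic rank unchanged.
#'
#' @param model an [ode_model]; parameters in `model$known` are excluded.
#' @param n_trials random specializations per rank decision.
#' @param seed integer seed.
#' @return an object of class `sio_report`.
#' @export
classify <- function(model, n_trials = 3, seed = 1) {
  set.seed(seed)
  aug <- augment(model)
  nxt <- aug$nxt
  trials <- lapply(seq_len(n_trials), function(i) .oi_rank_one(aug))
  rank <- max(vapply(trials, function(t) t$rank, numeric(1)))
  ord <- max(vapply(trials, function(t) t$order, numeric(1)))
  # column-deletion tests on each trial's assembled rows; a column is
  # deficient only if deletion leaves the rank unchanged in the best trial(s)
  col_rank <- function(j) {
    max(vapply(trials, function(t)
      rank_mod(t$rows[, -j, drop = FALSE], SIO_PRIME), numeric(1)))
  }
  defic <- vapply(seq_len(nxt), function(j) col_rank(j) == rank, logical(1))
  vars <- aug$states
  is_param <- seq_len(nxt) > aug$n
  up <- vars[is_param]
  structure(list(model = model$name,
                 fispo = rank == nxt,
                 rank = rank, nxt = nxt, order = ord,
                 identifiable = up[!defic[is_param]],
                 unidentifiable = up[defic[is_param]],
                 observable = vars[!is_param][!defic[!is_param]],
                 unobservable = vars[!is_param][defic[!is_param]],
                 evidence = list(seed = seed, n_trials = n_trials,
                                 prime = SIO_PRIME,
                                 points = lapply(trials, `[[`, "point"))),
            class = "sio_report")
}

#' @export
print.sio_report <- function(x, ...) {
  cat("SIO report for", x$model, "\n")
  cat(" generic rank ", x$rank, " of ", x$nxt,
      " (Lie order ", x$order, "): ",
      if (x$fispo) "FISPO" else "NOT FISPO", "\n", sep = "")
  if (length(x$unidentifiable))
    cat(" unidentifiable parameters:",
        paste(x$unidentifiable, collapse = ", "), "\n")
  if (length(x$unobservable))
    cat(" unobservable states:", paste(x$unobservable, collapse = ", "), "\n")
  invisible(x)
}

# ---- symbolic Lie-derivative rows -----------------------------------------

#' Symbolic observability-identifiability matrix
#'
#' Builds the Lie derivatives \eqn{L^0 g = g}, \eqn{L^i g = (\partial L^{i-1}
#' g / \partial \tilde x) \tilde f} and stacks their gradients. Fully
#' symbolic; intended for small models (an expression-size budget guards
#' against blow-up, setting `truncated` when exceeded).
#'
#' @param model an [ode_model].
#' @param max_order highest Lie-derivative order (capped at `nxt - 1`).
#' @param node_budget maximum total polynomial terms before truncation.
#' @return an object of class `oi_matrix`: `rows` (list of rows, each a list
#'   of `ratfun` entries), `vars`, `order`, `truncated`.
#' @export
lie_derivative_rows <- function(model, max_order = NULL, node_budget = 20000) {
  aug <- augment(model)
  vars <- aug$states
  if (is.null(max_order)) max_order <- aug$nxt - 1
  max_order <- min(max_order, aug$nxt - 1)
  allowed <- c(vars, model$known)
  fts <- lapply(aug$dynamics, function(e) rf_from_expr(e, allowed))
  L <- lapply(aug$outputs, function(g) rf_from_expr(g, allowed))
  rows <- list(); truncated <- FALSE
  sz <- function(r) nrow(r$num$E) + nrow(r$den$E)
  for (ord in 0:max_order) {
    grads <- lapply(L, function(l) lapply(vars, function(v) rf_deriv(l, v)))
    rows <- c(rows, grads)
    if (ord == max_order) break
    tot <- sum(vapply(unlist(grads, recursive = FALSE), sz, numeric(1)))
    if (tot > node_budget) { truncated <- TRUE; break }
    L <- lapply(grads, function(g) {
      acc <- rf_const(0)
      for (j in seq_along(vars))
        if (!rf_is_zero(g[[j]]) && !identical(aug$dynamics[[j]], quote(0)))
          acc <- rf_add(acc, rf_mul(g[[j]], fts[[j]]))
      acc
    })
  }
  structure(list(rows = rows, vars = vars,
                 order = length(rows) / length(aug$outputs) - 1,
                 truncated = truncated,
                 known_values = aug$known_values),
            class = "oi_matrix")
}

#' @export
print.oi_matrix <- function(x, ...) {
  cat("OI matrix: ", length(x$rows), " rows x ", length(x$vars),
      " columns (Lie order ", x$order, ")",
      if (x$truncated) " [truncated]" else "", "\n", sep = "")
  invisible(x)
}

# generic rank of a symbolic oi_matrix by modular specialization
oi_matrix_rank <- function(oi, n_trials = 3, p = SIO_PRIME) {
  nv <- length(oi$vars)
  best <- 0
  for (trial in seq_len(n_trials)) {
    for (att in 1:25) {
      pt <- stats::setNames(.sample_point(nv), oi$vars)
      kv <- oi$known_values %||% numeric()
      for (nm in names(kv)) pt[nm] <- .num_mod(kv[[nm]], p)
      M <- tryCatch({
        do.call(rbind, lapply(oi$rows, function(row)
          vapply(row, function(r) {
            den <- mp_eval_mod(r$den, pt, p)
            if (den == 0) stop("singular")
            (mp_eval_mod(r$num, pt, p) * .mod_inv(den, p)) %% p
          }, numeric(1))))
      }, error = function(e) NULL)
      if (!is.null(M)) break
    }
    if (is.null(M)) stop("no nonsingular specialization found")
    best <- max(best, rank_mod(M, p))
  }
  best
}
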