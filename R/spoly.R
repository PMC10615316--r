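# Polynomials in the state variables with coefficients drawn from a field of
# "constants": either plain doubles (fitted models) or exact rational
# functions of the parameters (symbolic models). Division, partial fractions
# and dictionary matching in the reformulation stage are written once over
# this layer; the numeric route uses a small tolerance where the exact route
# uses identity.

cf_is_num <- function(x) is.numeric(x)

cf_promote <- function(x) {
  if (cf_is_num(x)) {
    q <- .as_rat(x)
    rf_const(q[1], q[2])
  } else x
}

cf_bin <- function(a, b, fnum, frf) {
  if (cf_is_num(a) && cf_is_num(b)) return(fnum(a, b))
  frf(cf_promote(a), cf_promote(b))
}

cf_add <- function(a, b) cf_bin(a, b, `+`, rf_add)
cf_sub <- function(a, b) cf_bin(a, b, `-`, rf_sub)
cf_mul <- function(a, b) cf_bin(a, b, `*`, rf_mul)
cf_div <- function(a, b) cf_bin(a, b, `/`, rf_div)
cf_neg <- function(a) if (cf_is_num(a)) -a else rf_neg(a)

cf_is_zero <- function(a, tol = 0) {
  if (cf_is_num(a)) abs(a) <= tol else rf_is_zero(a)
}

cf_is_one <- function(a, tol = 0) {
  if (cf_is_num(a)) abs(a - 1) <= tol
  else rf_equal(a, rf_const(1))
}

cf_equal <- function(a, b, tol = 0) cf_is_zero(cf_sub(a, b), tol)

cf_to_string <- function(a, digits = 6) {
  if (cf_is_num(a)) {
    if (a == round(a) && abs(a) < 1e15) format(a, scientific = FALSE)
    else format(signif(a, digits), scientific = FALSE)
  } else rf_to_string(a)
}

cf_num_value <- function(a, env = list()) {
  if (cf_is_num(a)) a else rf_eval_num(a, env)
}

# ---- spoly -----------------------------------------------------------------

sp_make <- function(svars, E, cf, tol = 0) {
  p <- list(svars = svars, E = E, cf = cf)
  class(p) <- "spoly"
  sp_norm(p, tol)
}

sp_zero <- function(svars) {
  structure(list(svars = svars, E = matrix(0L, 0, length(svars)), cf = list()),
            class = "spoly")
}

sp_const <- function(svars, c0) {
  structure(list(svars = svars, E = matrix(0L, 1, length(svars)),
                 cf = list(c0)), class = "spoly")
}

sp_is_zero <- function(p) nrow(p$E) == 0

sp_norm <- function(p, tol = 0) {
  E <- p$E; cf <- p$cf
  if (nrow(E) > 1) {
    key <- apply(E, 1, paste, collapse = ",")
    grp <- split(seq_len(nrow(E)), key)
    if (length(grp) < nrow(E)) {
      idx <- vapply(grp, `[`, integer(1), 1)
      ncf <- lapply(grp, function(g) Reduce(cf_add, cf[g]))
      E <- E[idx, , drop = FALSE]; cf <- unname(ncf)
    }
  }
  keep <- !vapply(cf, cf_is_zero, logical(1), tol = tol)
  E <- E[keep, , drop = FALSE]; cf <- cf[keep]
  if (nrow(E) > 0) {
    o <- do.call(order, c(list(rowSums(E)), lapply(seq_len(ncol(E)),
                                                   function(j) E[, j])))
    E <- E[o, , drop = FALSE]; cf <- cf[o]
  }
  p$E <- E; p$cf <- cf
  p
}

sp_add <- function(a, b, tol = 0) {
  stopifnot(identical(a$svars, b$svars))
  sp_make(a$svars, rbind(a$E, b$E), c(a$cf, b$cf), tol)
}

sp_neg <- function(a) { a$cf <- lapply(a$cf, cf_neg); a }
sp_sub <- function(a, b, tol = 0) sp_add(a, sp_neg(b), tol)

sp_scale <- function(a, c0, tol = 0) {
  a$cf <- lapply(a$cf, cf_mul, b = c0)
  sp_norm(a, tol)
}

sp_mul <- function(a, b, tol = 0) {
  if (sp_is_zero(a) || sp_is_zero(b)) return(sp_zero(a$svars))
  na <- nrow(a$E); nb <- nrow(b$E)
  ia <- rep(seq_len(na), each = nb); ib <- rep(seq_len(nb), times = na)
  E <- a$E[ia, , drop = FALSE] + b$E[ib, , drop = FALSE]
  cf <- mapply(function(i, j) cf_mul(a$cf[[i]], b$cf[[j]]), ia, ib,
               SIMPLIFY = FALSE)
  sp_make(a$svars, E, cf, tol)
}

sp_deg <- function(a) if (sp_is_zero(a)) 0L else max(rowSums(a$E))

sp_deriv <- function(a, v) {
  j <- match(v, a$svars)
  keep <- a$E[, j] > 0
  if (!any(keep)) return(sp_zero(a$svars))
  E <- a$E[keep, , drop = FALSE]
  cf <- mapply(function(i, e) cf_mul(a$cf[[i]], e),
               which(keep), E[, j], SIMPLIFY = FALSE)
  E[, j] <- E[, j] - 1L
  sp_make(a$svars, E, cf)
}

# leading index under grlex with optional variable priority
sp_lead <- function(a, prio = NULL) {
  cols <- seq_len(ncol(a$E))
  if (!is.null(prio)) {
    pc <- match(intersect(prio, a$svars), a$svars)
    cols <- c(pc, setdiff(cols, pc))
  }
  o <- do.call(order, c(list(rowSums(a$E)), lapply(cols, function(j) a$E[, j])))
  o[length(o)]
}

# division: N = q*d + r (no term of r divisible by the leading monomial of d)
sp_divrem <- function(N, d, prio = NULL, tol = 0) {
  if (sp_is_zero(d)) stop("spoly division by zero")
  svars <- N$svars
  li <- sp_lead(d, prio)
  lE <- d$E[li, ]
  lc <- d$cf[[li]]
  q <- sp_zero(svars); r <- sp_zero(svars)
  w <- N
  guard <- 0
  while (!sp_is_zero(w)) {
    guard <- guard + 1
    if (guard > 5000) stop("spoly division did not terminate")
    i <- sp_lead(w, prio)
    tE <- w$E[i, ]
    if (all(tE >= lE)) {
      m <- structure(list(svars = svars,
                          E = matrix(as.integer(tE - lE), 1),
                          cf = list(cf_div(w$cf[[i]], lc))), class = "spoly")
      q <- sp_add(q, m, tol)
      w <- sp_sub(w, sp_mul(m, d, tol), tol)
    } else {
      m <- structure(list(svars = svars, E = w$E[i, , drop = FALSE],
                          cf = w$cf[i]), class = "spoly")
      r <- sp_add(r, m, tol)
      w <- sp_sub(w, m, tol)
    }
  }
  list(q = q, r = r)
}

sp_equal <- function(a, b, tol = 0) sp_is_zero(sp_sub(a, b, tol))

# convert an exact mpoly in states+params into an spoly over `states` with
# ratfun coefficients in the parameters
sp_from_mp <- function(p, states) {
  if (mp_is_zero(p)) return(sp_zero(states))
  sidx <- match(states, p$vars)
  E <- matrix(0L, nrow(p$E), length(states))
  for (k in seq_along(states))
    if (!is.na(sidx[k])) E[, k] <- p$E[, sidx[k]]
  pidx <- which(!(p$vars %in% states))
  cf <- lapply(seq_len(nrow(p$E)), function(i) {
    co <- mp_make(p$vars[pidx],
                  p$E[i, pidx, drop = FALSE], p$cn[i], p$cd[i])
    rf_make(co)
  })
  sp_make(states, E, cf)
}

# numeric spoly from an exact mpoly by evaluating parameter coefficients
sp_from_mp_numeric <- function(p, states, param_values) {
  sp <- sp_from_mp(p, states)
  sp$cf <- lapply(sp$cf, function(c0) cf_num_value(c0, as.list(param_values)))
  sp_norm(sp, 0)
}

sp_to_string <- function(a, digits = 6) {
  if (sp_is_zero(a)) return("0")
  o <- rev(seq_len(nrow(a$E)))
  out <- ""
  for (i in o) {
    mono <- character(0)
    for (k in seq_along(a$svars)) {
      e <- a$E[i, k]
      if (e == 1) mono <- c(mono, a$svars[k])
      else if (e > 1) mono <- c(mono, paste0(a$svars[k], "^", e))
    }
    c0 <- a$cf[[i]]
    neg <- cf_is_num(c0) && c0 < 0
    if (neg) c0 <- -c0
    cs <- cf_to_string(c0, digits)
    if (grepl("[-+*/^ ]", substring(cs, 2))) cs <- paste0("(", cs, ")")
    term <- if (length(mono) == 0) cs
            else if (cf_is_one(c0)) paste(mono, collapse = "*")
            else paste(c(cs, mono), collapse = "*")
    out <- if (out == "") paste0(if (neg) "-" else "", term)
           else paste0(out, if (neg) " - " else " + ", term)
  }
  out
}

# evaluate on a data matrix X (columns = svars); coefficients must be numeric
sp_eval_rows <- function(a, X) {
  if (sp_is_zero(a)) return(rep(0, nrow(X)))
  acc <- rep(0, nrow(X))
  for (i in seq_len(nrow(a$E))) {
    v <- rep(a$cf[[i]], nrow(X))
    for (k in seq_along(a$svars)) {
      e <- a$E[i, k]
      if (e > 0) v <- v * X[, k]^e
    }
    acc <- acc + v
  }
  acc
}

# monomial of an spoly row as readable key
sp_mono_string <- function(a, i) {
  mono <- character(0)
  for (k in seq_along(a$svars)) {
    e <- a$E[i, k]
    if (e == 1) mono <- c(mono, a$svars[k])
    else if (e > 1) mono <- c(mono, paste0(a$svars[k], "^", e))
  }
  if (!length(mono)) "1" else paste(mono, collapse = "*")
}
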