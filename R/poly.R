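# Exact multivariate polynomial arithmetic over the rationals.
#
# A polynomial is a list(vars, E, cn, cd): `vars` is the character vector of
# variable names, `E` an integer exponent matrix (one row per term, one column
# per variable), and `cn`/`cd` hold each term's coefficient as a reduced
# fraction cn/cd (cd > 0). Terms are kept merged, nonzero, and sorted in
# graded-lexicographic order. Coefficient arithmetic is exact; magnitudes are
# guarded against exceeding the range where double-precision integers are
# exact (2^52), which is ample for the model algebra handled here.

QMAX <- 2^52

.q_gcd <- function(a, b) {
  a <- abs(a); b <- abs(b)
  while (any(b > 0)) {
    t <- b
    b <- ifelse(b > 0, a %% b, 0)
    a <- t
  }
  ifelse(a == 0, 1, a)
}

.q_reduce <- function(cn, cd) {
  if (any(cd == 0)) stop("zero denominator in rational coefficient")
  s <- ifelse(cd < 0, -1, 1)
  cn <- cn * s; cd <- cd * s
  g <- .q_gcd(cn, cd)
  cn <- cn / g; cd <- cd / g
  if (any(abs(cn) > QMAX) || any(cd > QMAX))
    stop("rational coefficient overflow (exceeds exact double-integer range)")
  list(cn = cn, cd = cd)
}

# double -> exact rational via continued fractions (exact for integers and
# simple fractions such as 8/3; tol is relative)
.as_rat <- function(x, tol = 1e-11) {
  if (length(x) != 1 || !is.finite(x)) stop("cannot rationalize: ", x)
  if (x == round(x) && abs(x) <= QMAX) return(c(x, 1))
  sign <- if (x < 0) -1 else 1
  z <- abs(x)
  p0 <- 0; q0 <- 1; p1 <- 1; q1 <- 0; a <- z
  for (i in 1:64) {
    ai <- floor(a)
    p2 <- ai * p1 + p0; q2 <- ai * q1 + q0
    if (q2 > 1e15) break
    p0 <- p1; q0 <- q1; p1 <- p2; q1 <- q2
    if (abs(p1 / q1 - z) <= tol * max(z, 1)) break
    if (a - ai < 1e-14) break
    a <- 1 / (a - ai)
  }
  c(sign * p1, q1)
}

mp_make <- function(vars, E, cn, cd) {
  p <- list(vars = vars, E = E, cn = cn, cd = cd)
  class(p) <- "mpoly"
  mp_norm(p)
}

mp_zero <- function(vars = character()) {
  p <- list(vars = vars, E = matrix(0L, 0, length(vars)), cn = numeric(0),
            cd = numeric(0))
  class(p) <- "mpoly"
  p
}

mp_const <- function(num, den = 1, vars = character()) {
  q <- .q_reduce(num, den)
  if (q$cn == 0) return(mp_zero(vars))
  p <- list(vars = vars, E = matrix(0L, 1, length(vars)), cn = q$cn, cd = q$cd)
  class(p) <- "mpoly"
  p
}

mp_var <- function(v, pow = 1L) {
  p <- list(vars = v, E = matrix(as.integer(pow), 1, 1), cn = 1, cd = 1)
  class(p) <- "mpoly"
  p
}

mp_is_zero <- function(p) nrow(p$E) == 0

# grlex order key (ascending); `prio` optionally promotes some variables for
# the lexicographic tie-break (first in `prio` = most significant)
.mp_order <- function(E, vars, prio = NULL) {
  if (nrow(E) == 0) return(integer(0))
  deg <- rowSums(E)
  cols <- if (is.null(prio)) order(vars) else {
    c(match(intersect(prio, vars), vars),
      setdiff(order(vars), match(intersect(prio, vars), vars)))
  }
  args <- c(list(deg), lapply(cols, function(j) E[, j]))
  do.call(order, args)
}

mp_norm <- function(p) {
  E <- p$E; cn <- p$cn; cd <- p$cd
  if (length(p$vars) == 0 && ncol(E) != 0) E <- matrix(0L, nrow(E), 0)
  # drop unused variables to keep representations small
  if (ncol(E) > 0) {
    used <- colSums(E != 0) > 0
    if (!all(used)) {
      p$vars <- p$vars[used]
      E <- E[, used, drop = FALSE]
    }
  }
  if (nrow(E) > 1) {
    key <- apply(E, 1, paste, collapse = ",")
    grp <- split(seq_len(nrow(E)), key)
    if (length(grp) < nrow(E)) {
      idx <- vapply(grp, `[`, integer(1), 1)
      ncn <- numeric(length(grp)); ncd <- numeric(length(grp))
      for (i in seq_along(grp)) {
        g <- grp[[i]]
        n <- cn[g[1]]; d <- cd[g[1]]
        for (j in g[-1]) {
          n2 <- n * cd[j] + cn[j] * d
          d2 <- d * cd[j]
          q <- .q_reduce(n2, d2)
          n <- q$cn; d <- q$cd
        }
        ncn[i] <- n; ncd[i] <- d
      }
      E <- E[idx, , drop = FALSE]
      cn <- ncn; cd <- ncd
    }
  }
  keep <- cn != 0
  E <- E[keep, , drop = FALSE]; cn <- cn[keep]; cd <- cd[keep]
  o <- .mp_order(E, p$vars)
  p$E <- E[o, , drop = FALSE]; p$cn <- cn[o]; p$cd <- cd[o]
  p
}

.mp_align <- function(a, b) {
  vars <- union(a$vars, b$vars)
  ext <- function(p) {
    E <- matrix(0L, nrow(p$E), length(vars))
    if (length(p$vars)) E[, match(p$vars, vars)] <- p$E
    p$E <- E; p$vars <- vars
    p
  }
  list(a = ext(a), b = ext(b), vars = vars)
}

mp_add <- function(a, b) {
  al <- .mp_align(a, b)
  mp_make(al$vars, rbind(al$a$E, al$b$E), c(al$a$cn, al$b$cn),
          c(al$a$cd, al$b$cd))
}

mp_neg <- function(p) { p$cn <- -p$cn; p }
mp_sub <- function(a, b) mp_add(a, mp_neg(b))

mp_scale <- function(p, num, den = 1) {
  if (num == 0) return(mp_zero(p$vars))
  q <- .q_reduce(p$cn * num, p$cd * den)
  p$cn <- q$cn; p$cd <- q$cd
  p
}

mp_mul <- function(a, b) {
  if (mp_is_zero(a) || mp_is_zero(b)) return(mp_zero(union(a$vars, b$vars)))
  al <- .mp_align(a, b)
  na <- nrow(al$a$E); nb <- nrow(al$b$E)
  ia <- rep(seq_len(na), each = nb); ib <- rep(seq_len(nb), times = na)
  E <- al$a$E[ia, , drop = FALSE] + al$b$E[ib, , drop = FALSE]
  q <- .q_reduce(al$a$cn[ia] * al$b$cn[ib], al$a$cd[ia] * al$b$cd[ib])
  mp_make(al$vars, E, q$cn, q$cd)
}

mp_pow <- function(p, k) {
  k <- as.integer(k)
  if (k < 0) stop("negative power on polynomial")
  out <- mp_const(1)
  base <- p
  while (k > 0) {
    if (k %% 2L == 1L) out <- mp_mul(out, base)
    k <- k %/% 2L
    if (k > 0) base <- mp_mul(base, base)
  }
  out
}

mp_deriv <- function(p, v) {
  j <- match(v, p$vars)
  if (is.na(j)) return(mp_zero())
  keep <- p$E[, j] > 0
  if (!any(keep)) return(mp_zero())
  E <- p$E[keep, , drop = FALSE]
  q <- .q_reduce(p$cn[keep] * E[, j], p$cd[keep])
  E[, j] <- E[, j] - 1L
  mp_make(p$vars, E, q$cn, q$cd)
}

mp_subs <- function(p, v, repl) {
  j <- match(v, p$vars)
  if (is.na(j)) return(p)
  out <- mp_zero()
  for (i in seq_len(nrow(p$E))) {
    term <- mp_const(p$cn[i], p$cd[i])
    for (k in seq_along(p$vars)) {
      e <- p$E[i, k]
      if (e == 0) next
      f <- if (k == j) mp_pow(repl, e) else mp_var(p$vars[k], e)
      term <- mp_mul(term, f)
    }
    out <- mp_add(out, term)
  }
  out
}

mp_equal <- function(a, b) mp_is_zero(mp_sub(a, b))

mp_total_deg <- function(p, vars = NULL) {
  if (mp_is_zero(p)) return(0L)
  E <- p$E
  if (!is.null(vars)) {
    keep <- p$vars %in% vars
    E <- E[, keep, drop = FALSE]
  }
  if (ncol(E) == 0) return(0L)
  max(rowSums(E))
}

mp_eval_num <- function(p, env) {
  if (mp_is_zero(p)) return(0)
  vals <- vapply(p$vars, function(v) env[[v]], numeric(1))
  mono <- if (ncol(p$E)) {
    apply(p$E, 1, function(e) prod(vals^e))
  } else rep(1, nrow(p$E))
  sum(p$cn / p$cd * mono)
}

# leading term under grlex with optional variable priority; returns index
mp_lead <- function(p, prio = NULL) {
  o <- .mp_order(p$E, p$vars, prio)
  o[length(o)]
}

# multivariate division of N by a single divisor d (grlex, optional priority):
# N = q*d + r with no term of r divisible by the leading monomial of d
mp_divrem <- function(N, d, prio = NULL) {
  if (mp_is_zero(d)) stop("division by zero polynomial")
  al <- .mp_align(N, d)
  vars <- al$vars
  d <- al$b
  li <- mp_lead(d, prio)
  lE <- d$E[li, ]
  lcn <- d$cn[li]; lcd <- d$cd[li]
  q <- mp_zero(vars); r <- mp_zero(vars)
  w <- al$a
  guard <- 0L
  while (!mp_is_zero(w)) {
    guard <- guard + 1L
    if (guard > 20000L) stop("division did not terminate")
    w <- .mp_align(w, mp_zero(vars))$a   # keep var alignment stable
    o <- .mp_order(w$E, w$vars, prio)
    i <- o[length(o)]
    tE <- w$E[i, match(vars, w$vars)]
    tE[is.na(tE)] <- 0L
    if (all(tE >= lE)) {
      cf <- .q_reduce(w$cn[i] * lcd, w$cd[i] * lcn)
      m <- mp_make(vars, matrix(as.integer(tE - lE), 1), cf$cn, cf$cd)
      q <- mp_add(q, m)
      w <- mp_sub(w, mp_mul(m, d))
    } else {
      m <- mp_make(w$vars, w$E[i, , drop = FALSE], w$cn[i], w$cd[i])
      r <- mp_add(r, m)
      w <- mp_sub(w, m)
    }
  }
  list(q = q, r = r)
}

mp_divides <- function(d, N, prio = NULL) mp_is_zero(mp_divrem(N, d, prio)$r)

# exact evaluation modulo a prime (point: named integer vector)
.mod_inv <- function(a, p) {
  a <- a %% p
  if (a == 0) stop("modular inverse of zero")
  # extended Euclid
  r0 <- p; r1 <- a; s0 <- 0; s1 <- 1
  while (r1 != 0) {
    qq <- floor(r0 / r1)
    tmp <- r0 - qq * r1; r0 <- r1; r1 <- tmp
    tmp <- s0 - qq * s1; s0 <- s1; s1 <- tmp
  }
  s0 %% p
}

mp_eval_mod <- function(p, point, prime) {
  if (mp_is_zero(p)) return(0)
  acc <- 0
  for (i in seq_len(nrow(p$E))) {
    t <- (p$cn[i] %% prime) * .mod_inv(p$cd[i] %% prime, prime) %% prime
    t <- t %% prime
    for (k in seq_along(p$vars)) {
      e <- p$E[i, k]
      if (e == 0) next
      b <- point[[p$vars[k]]] %% prime
      pw <- 1
      bb <- b; ee <- e
      while (ee > 0) {
        if (ee %% 2 == 1) pw <- (pw * bb) %% prime
        bb <- (bb * bb) %% prime
        ee <- ee %/% 2
      }
      t <- (t * pw) %% prime
    }
    acc <- (acc + t) %% prime
  }
  acc
}

# common monomial + numeric content: p = content * core, content a single term
mp_content <- function(p) {
  if (mp_is_zero(p)) return(list(content = mp_const(1), core = p))
  e <- if (ncol(p$E)) apply(p$E, 2, min) else integer(0)
  gn <- Reduce(.q_gcd, abs(p$cn))
  gd <- Reduce(.q_gcd, p$cd)  # lcm would be exact; gcd of denominators is a
  # conservative normalizer: use lcm for a true content
  l <- p$cd[1]
  for (d in p$cd[-1]) l <- l / .q_gcd(l, d) * d
  sgn <- if (p$cn[length(p$cn)] < 0) -1 else 1
  content <- mp_make(p$vars, matrix(as.integer(e), 1), sgn * gn, l)
  core <- mp_make(p$vars, sweep(p$E, 2, as.integer(e)),
                  p$cn / (sgn * gn) * (l / p$cd), rep(1, length(p$cn)))
  list(content = content, core = core)
}

# render as conventional infix string (R-parseable)
.q_str <- function(cn, cd) {
  if (cd == 1) {
    format(cn, scientific = FALSE)
  } else {
    paste0("(", format(cn, scientific = FALSE), "/",
           format(cd, scientific = FALSE), ")")
  }
}

mp_to_string <- function(p) {
  if (mp_is_zero(p)) return("0")
  o <- rev(.mp_order(p$E, p$vars))  # descending grlex for readability
  parts <- character(0)
  for (i in o) {
    mono <- character(0)
    for (k in seq_along(p$vars)) {
      e <- p$E[i, k]
      if (e == 1) mono <- c(mono, p$vars[k])
      else if (e > 1) mono <- c(mono, paste0(p$vars[k], "^", e))
    }
    cn <- p$cn[i]; cd <- p$cd[i]
    neg <- cn < 0
    cn <- abs(cn)
    cstr <- .q_str(cn, cd)
    term <- if (length(mono) == 0) cstr
            else if (cn == 1 && cd == 1) paste(mono, collapse = "*")
            else paste(c(cstr, mono), collapse = "*")
    parts <- c(parts, if (length(parts) == 0) {
      if (neg) paste0("-", term) else term
    } else {
      paste0(if (neg) " - " else " + ", term)
    })
  }
  paste(parts, collapse = "")
}
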