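#' Packaged case studies
#'
#' Six benchmark systems ship with the package, spanning polynomial dynamics
#' (Lorenz), Michaelis-Menten/Monod saturation (Microbial), Hill regulation
#' (Bacterial competence), saturating feedback (Crypt), quorum-sensing
#' modulation (Immunity) and a seven-pool glycolytic oscillator. Each case
#' carries the ground-truth model with nominal parameter values and initial
#' conditions, and (where relevant) the candidate structure recovered by
#' implicit sparse regression, used to exercise the identifiability and
#' reformulation stages.
#'
#' @param id case identifier; one of `case_ids()`.
#' @return a list of class `case_study` with elements `id`, `gt_model`
#'   (an [ode_model]), `cm_model` (an [ode_model] or NULL), `default_params`,
#'   `default_x0`, `expected_fispo`, `expected_degrees` (max total degree in
#'   the states of N and D of the implicit rational form), and the default
#'   discovery settings `library_degree`, `t_end`, `n_points`, `n_traj`.
#' @export
get_case <- function(id) {
  reg <- .case_registry()
  if (!id %in% names(reg))
    stop("unknown case id: ", id, "; valid ids: ",
         paste(names(reg), collapse = ", "))
  e <- reg[[id]]
  dir <- system.file("extdata", "models", package = "sindysio")
  gt <- read_model(file.path(dir, e$gt))
  cm <- if (!is.null(e$cm) && !is.na(e$cm))
    read_model(file.path(dir, e$cm)) else NULL
  structure(list(id = id, gt_model = gt, cm_model = cm,
                 default_params = gt$param_values, default_x0 = gt$x0,
                 expected_fispo = e$expected_fispo,
                 expected_degrees = unlist(e$expected_degrees),
                 library_degree = e$library_degree,
                 t_end = e$t_end, n_points = e$n_points, n_traj = e$n_traj),
            class = "case_study")
}

#' @rdname get_case
#' @export
case_ids <- function() names(.case_registry())

.case_registry <- function() {
  path <- system.file("extdata", "models", "registry.json",
                      package = "sindysio")
  jsonlite::read_json(path)
}

#' @export
print.case_study <- function(x, ...) {
  cat("case study:", x$id, "\n")
  cat(" ground truth: ", length(x$gt_model$states), " states, ",
      length(x$gt_model$params), " parameters; FISPO expected: ",
      x$expected_fispo, "\n", sep = "")
  cat(" implicit-form degrees (N, D): ",
      paste(x$expected_degrees, collapse = ", "), "\n", sep = "")
  if (!is.null(x$cm_model))
    cat(" candidate structure: ", length(x$cm_model$params),
        " coefficients\n", sep = "")
  invisible(x)
}
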