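#' Declare the regression model
#'
#' Declares the outcome, the categorical geographic factors with their
#' reference levels, the unit-scaled environmental covariates, the
#' first-order interaction pairs modelled as exchangeable random effects,
#' and whether the spatially structured residual is included.
#'
#' @param outcome name of the outcome column (an obesity rate, %).
#' @param factors named character vector: names are factor columns, values
#'   their reference levels (omitted from the dummy coding). Order determines
#'   design-column order.
#' @param covariates character vector of numeric indicator columns; each is
#'   rescaled to `[0, 1]` by [scale_unit()] when the design is built.
#' @param interactions list of length-2 character vectors naming factor
#'   pairs, or `"all"` for every pairwise combination of `factors` (the six
#'   pairs when four factors are declared). `NULL` for none.
#' @param spatial include the ICAR spatial effect (default `TRUE`).
#' @returns A `model_spec` object.
#' @examples
#' model_spec("obesity_persons",
#'            factors = c(urbanicity = "1", division = "New England"),
#'            covariates = "inactivity", interactions = "all")
#' @export
model_spec <- function(outcome, factors, covariates = character(0),
                       interactions = NULL, spatial = TRUE) {
  stopifnot(is.character(outcome), length(outcome) == 1)
  if (length(factors) && is.null(names(factors)))
    stop("factors must be a named vector: names = columns, values = reference levels")
  if (identical(interactions, "all")) {
    fn <- names(factors)
    interactions <- if (length(fn) >= 2) utils::combn(fn, 2, simplify = FALSE)
    else list()
  }
  interactions <- interactions %||% list()
  for (pair in interactions) {
    if (length(pair) != 2 || !all(pair %in% names(factors)))
      stop("interaction pairs must reference declared factors")
  }
  structure(list(outcome = outcome, factors = factors,
                 covariates = covariates, interactions = interactions,
                 spatial = isTRUE(spatial)),
            class = "model_spec")
}

#' @export
print.model_spec <- function(x, ...) {
  cat("<model_spec>\n outcome:     ", x$outcome,
      "\n factors:     ", paste0(names(x$factors), " (ref ", x$factors, ")",
                                 collapse = ", "),
      "\n covariates:  ", if (length(x$covariates))
        paste(x$covariates, collapse = ", ") else "(none)",
      "\n interactions:", length(x$interactions), "pair(s)",
      "\n spatial:     ", x$spatial, "\n")
  invisible(x)
}

#' Build the fixed-effect design matrix and interaction incidence
#'
#' Dummy-codes each declared factor with its reference level omitted
#' (columns ordered by the remaining level order), appends the unit-scaled
#' covariates, and maps each county to its cell in every interaction block.
#' Column order is intercept, factor dummies in declaration order, then
#' covariates — matching the published table layout.
#'
#' @param data data frame of county rows.
#' @param spec a [model_spec()].
#' @returns A `car_design` object: list with `X` (n x p matrix with named
#'   columns), `interaction` (list per pair: `cell` 1-based index vector,
#'   `labels`, `n_cells`), and `spec`.
#' @export
build_design <- function(data, spec) {
  stopifnot(is.data.frame(data), inherits(spec, "model_spec"))
  used <- c(names(spec$factors), spec$covariates)
  missing_cols <- setdiff(used, names(data))
  if (length(missing_cols))
    stop("columns not in data: ", paste(missing_cols, collapse = ", "))
  if (anyNA(data[used]))
    stop("missing values in model columns")
  n <- nrow(data)
  X <- matrix(1, n, 1, dimnames = list(NULL, "(Intercept)"))
  for (f in names(spec$factors)) {
    ref <- spec$factors[[f]]
    v <- as.character(data[[f]])
    lv <- level_order(data[[f]])
    if (!ref %in% lv)
      stop("reference level '", ref, "' absent from factor '", f, "'")
    lv <- lv[lv %in% v]  # unobserved declared levels carry no dummy
    if (!ref %in% v)
      stop("reference level '", ref, "' has no observations in factor '",
           f, "'")
    for (l in setdiff(lv, ref)) {
      X <- cbind(X, as.numeric(v == l))
      colnames(X)[ncol(X)] <- paste0(f, ":", l)
    }
  }
  for (cv in spec$covariates) {
    X <- cbind(X, scale_unit(data[[cv]]))
    colnames(X)[ncol(X)] <- cv
  }
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    dep <- colnames(X)[qrX$pivot[(qrX$rank + 1):ncol(X)]]
    stop("collinear design columns: ", paste(dep, collapse = ", "))
  }
  interaction <- lapply(spec$interactions, function(pair) {
    lab <- paste(as.character(data[[pair[1]]]),
                 as.character(data[[pair[2]]]), sep = " * ")
    labels <- sort(unique(lab))  # observed cells only
    list(pair = pair, cell = match(lab, labels), labels = labels,
         n_cells = length(labels))
  })
  names(interaction) <- vapply(spec$interactions,
                               function(p) paste(p, collapse = "*"),
                               character(1))
  structure(list(X = X, interaction = interaction, spec = spec, n = n),
            class = "car_design")
}

#' @export
print.car_design <- function(x, ...) {
  cat("<car_design> ", x$n, " counties, ", ncol(x$X),
      " fixed-effect columns, ", length(x$interaction),
      " interaction block(s)\n", sep = "")
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
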