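#' Declare an occupancy model structure
#'
#' A model spec names the terms entering the logit-linear predictor of
#' occupancy (psi) and of detection (p). Recognised psi terms:
#'
#' * `"Habitat"` — cell-means coding over all five habitats (one indicator
#'   column per level, no intercept);
#' * `"Residential"` — cell-means coding over the three residential levels;
#' * `"Food"` — the binary supplementary-food indicator;
#' * `"Area"` — proportion of forest fragment within the site buffer;
#' * `"."` — intercept only (constant psi).
#'
#' Detection supports `"."` (constant p, the study design) and, for
#' structural completeness, `"Food"`/`"Area"` site covariates.
#'
#' @param psi Character vector of psi terms, or `"."`.
#' @param p Character vector of p terms (default `"."`).
#' @param name Optional display name; defaults to the
#'   `"psi(...),p(.)"` convention.
#' @return An object of class `occu_model_spec` with elements `name`,
#'   `psi_terms`, `p_terms`.
#' @examples
#' model_spec(c("Residential", "Food", "Area"))
#' parse_model_name("psi(Habitat)p(.)")
#' @export
model_spec <- function(psi = ".", p = ".", name = NULL) {
  known_psi <- c(".", "Habitat", "Residential", "Food", "Area")
  known_p <- c(".", "Food", "Area")
  psi <- as.character(psi)
  p <- as.character(p)
  if (!length(psi)) psi <- "."
  if (!length(p)) p <- "."
  bad <- setdiff(psi, known_psi)
  if (length(bad)) stop("unknown psi term(s): ", paste(bad, collapse = ", "),
    call. = FALSE)
  bad <- setdiff(p, known_p)
  if (length(bad)) stop("unknown p term(s): ", paste(bad, collapse = ", "),
    call. = FALSE)
  if ("." %in% psi && length(psi) > 1L) {
    stop("psi '.' cannot be combined with other terms", call. = FALSE)
  }
  if ("Habitat" %in% psi && "Residential" %in% psi) {
    stop("Habitat and Residential cell-means terms are mutually exclusive",
      call. = FALSE)
  }
  if (is.null(name)) {
    name <- sprintf(
      "psi(%s),p(%s)",
      paste(psi, collapse = "+"), paste(p, collapse = "+")
    )
  }
  structure(list(name = name, psi_terms = psi, p_terms = p),
    class = "occu_model_spec")
}

#' @export
print.occu_model_spec <- function(x, ...) {
  cat("occupancy model spec:", x$name, "\n")
  invisible(x)
}

#' Parse a "psi(...),p(...)" model name into a spec
#'
#' Accepts the conventional names, e.g. `"psi(Residential+Food+Area),p(.)"`
#' or `"psi(Habitat)p(.)"` (the comma is optional).
#'
#' @param name Model name string.
#' @return An [model_spec()] object.
#' @export
parse_model_name <- function(name) {
  m <- regmatches(name, regexec(
    "^psi\\(([^)]*)\\),?p\\(([^)]*)\\)$", trimws(name)
  ))[[1]]
  if (length(m) != 3L) {
    stop("cannot parse model name: ", dQuote(name), call. = FALSE)
  }
  split_terms <- function(s) {
    s <- trimws(strsplit(s, "+", fixed = TRUE)[[1]])
    if (!length(s)) "." else s
  }
  model_spec(split_terms(m[2]), split_terms(m[3]), name = trimws(name))
}

#' The two whole-city models
#'
#' The constant model `psi(.),p(.)` and the habitat cell-means model
#' `psi(Habitat)p(.)` compared over all five habitat types.
#'
#' @return List of two [model_spec()] objects.
#' @export
all_habitats_model_set <- function() {
  list(
    model_spec("Habitat", name = "psi(Habitat)p(.)"),
    model_spec(".", name = "psi(.)p(.)")
  )
}

#' The eight residential candidate models
#'
#' All combinations of the residential cell-means term, the food indicator
#' and the forest-area covariate that were compared for the residential
#' subset, each with constant detection.
#'
#' @return List of eight [model_spec()] objects.
#' @export
residential_model_set <- function() {
  lapply(
    list(
      c("Residential", "Food", "Area"),
      "Residential",
      ".",
      "Area",
      "Food",
      c("Food", "Area"),
      c("Residential", "Area"),
      c("Residential", "Food")
    ),
    model_spec
  )
}

# one block of design columns for a single term
term_columns <- function(term, data) {
  sites <- data$sites
  n <- nrow(sites)
  switch(term,
    "." = matrix(1, n, 1L, dimnames = list(NULL, "(Intercept)")),
    "Habitat" = ,
    "Residential" = {
      lev <- if (term == "Habitat") habitat_levels() else residential_levels()
      lev <- lev[lev %in% as.character(unique(sites$habitat))]
      if (!length(lev)) {
        stop("no sites in any level of term ", dQuote(term), call. = FALSE)
      }
      X <- vapply(lev, function(l) as.numeric(sites$habitat == l),
        numeric(n))
      matrix(X, n, length(lev), dimnames = list(NULL, lev))
    },
    "Food" = {
      if (is.null(sites$food)) stop("covariate 'food' absent", call. = FALSE)
      matrix(sites$food, n, 1L, dimnames = list(NULL, "Food"))
    },
    "Area" = {
      if (is.null(sites$forest_area)) {
        stop("covariate 'forest_area' absent", call. = FALSE)
      }
      matrix(sites$forest_area, n, 1L, dimnames = list(NULL, "Area"))
    },
    stop("unknown term: ", term, call. = FALSE)
  )
}

#' Build psi and p design matrices for a model spec
#'
#' Habitat terms enter as cell means (one indicator column per level, no
#' intercept); covariates enter as supplied; an intercept-only spec gives a
#' single all-ones column. Columns follow the spec's term order. A numeric
#' covariate that is zero at every site (or an empty habitat cell) is a
#' separation hazard for the likelihood; such columns are reported in the
#' `"singular"` attribute of the returned matrix rather than silently
#' dropped.
#'
#' @param data An [occu_data] object.
#' @param spec An [model_spec()] object (or model-name string).
#' @return List with `X_psi` (n x q), `X_p` (n x r) and `K` (= q + r, the
#'   coefficient count).
#' @export
build_design_matrices <- function(data, spec) {
  stopifnot(inherits(data, "occu_data"))
  if (is.character(spec)) spec <- parse_model_name(spec)
  stopifnot(inherits(spec, "occu_model_spec"))
  bind <- function(terms) {
    X <- do.call(cbind, lapply(terms, term_columns, data = data))
    zero <- colnames(X)[colSums(abs(X)) == 0]
    if (length(zero)) {
      warning("design column(s) identically zero (separation hazard): ",
        paste(zero, collapse = ", "), call. = FALSE)
      attr(X, "singular") <- zero
    }
    X
  }
  X_psi <- bind(spec$psi_terms)
  X_p <- bind(spec$p_terms)
  list(X_psi = X_psi, X_p = X_p, K = ncol(X_psi) + ncol(X_p))
}
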