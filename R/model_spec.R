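#' Candidate model specification
#'
#' Describes a candidate covariate structure for either the landscape
#' (use-availability, mixed logistic) or patch (step-selection, conditional
#' logistic) scale. The base habitat block is aspect + elevation +
#' elevation^2 + snowmelt + snowmelt^2 (plus step length at the patch scale,
#' which is carried by all patch-scale models as a nuisance covariate).
#' Forage components are any subset of biomass (optionally quadratic), DN
#' and DE; an insect index can be added with interactions against forage
#' components. Structural rules: biomass^2 never appears without biomass,
#' and interactions never without both main effects.
#'
#' @param scale `"landscape"` or `"patch"`.
#' @param period Period label (bookkeeping only).
#' @param forage Character subset of `c("biomass", "dn", "de")`.
#' @param biomass_quad Include biomass^2? (requires `"biomass"` in
#'   `forage`).
#' @param insect `NULL`, `"mi"` or `"oi"`.
#' @param insect_interactions Forage components interacting with the insect
#'   index (subset of `forage`; `"biomass"` brings the quadratic interaction
#'   along when `biomass_quad` is set).
#' @param base Include the base habitat block? (`FALSE` gives the null
#'   model.)
#' @param label Optional display label; a compact one is built by default.
#' @return A `model_spec` object.
#' @export
model_spec <- function(scale = c("landscape", "patch"), period = "all",
                       forage = character(0), biomass_quad = FALSE,
                       insect = NULL, insect_interactions = character(0),
                       base = TRUE, label = NULL) {
  scale <- match.arg(scale)
  forage <- intersect(c("biomass", "dn", "de"), forage)
  if (biomass_quad && !"biomass" %in% forage) {
    stopf("biomass_quad requires biomass among the forage components")
  }
  if (length(insect_interactions)) {
    if (is.null(insect)) stopf("insect interactions require an insect main effect")
    if (!all(insect_interactions %in% forage)) {
      stopf("insect interactions require the forage main effects: %s",
            paste(setdiff(insect_interactions, forage), collapse = ", "))
    }
  }
  sp <- structure(
    list(scale = scale, period = period, forage = forage,
         biomass_quad = biomass_quad, insect = insect,
         insect_interactions = insect_interactions, base = base),
    class = "model_spec"
  )
  sp$label <- label %||% spec_label(sp)
  sp
}

spec_label <- function(spec) {
  if (!spec$base && !length(spec$forage) && is.null(spec$insect)) return("Null")
  parts <- if (spec$base) "Base habitat" else "Null"
  fl <- c(BM = "biomass", DN = "dn", DE = "de")
  for (f in spec$forage) {
    nm <- names(fl)[fl == f]
    parts <- c(parts, nm)
    if (f == "biomass" && spec$biomass_quad) parts <- c(parts, "BM^2")
  }
  if (!is.null(spec$insect)) {
    ins <- toupper(spec$insect)
    parts <- c(parts, ins)
    for (f in spec$insect_interactions) {
      nm <- names(fl)[fl == f]
      parts <- c(parts, paste0(ins, "*", nm))
      if (f == "biomass" && spec$biomass_quad) {
        parts <- c(parts, paste0(ins, "*BM^2"))
      }
    }
  }
  paste(parts, collapse = " + ")
}

#' Model terms implied by a specification
#'
#' Term names reference standardised design-row columns; `aspect` expands to
#' dummies at model-matrix time and `a:b` denotes a product of standardised
#' columns. The landscape null model is intercept-only; the patch null model
#' carries only the step-length nuisance term (every patch-scale model
#' includes step length).
#'
#' @param spec A [model_spec()].
#' @return Character vector of term names.
#' @export
spec_terms <- function(spec) {
  terms <- character(0)
  if (spec$base) {
    terms <- c("aspect", "elevation", "elevation_sq", "snowmelt", "snowmelt_sq")
  }
  for (f in spec$forage) {
    terms <- c(terms, f)
    if (f == "biomass" && spec$biomass_quad) terms <- c(terms, "biomass_sq")
  }
  if (!is.null(spec$insect)) {
    terms <- c(terms, spec$insect)
    for (f in spec$insect_interactions) {
      terms <- c(terms, paste0(spec$insect, ":", f))
      if (f == "biomass" && spec$biomass_quad) {
        terms <- c(terms, paste0(spec$insect, ":biomass_sq"))
      }
    }
  }
  if (spec$scale == "patch") terms <- c(terms, "step_length")
  terms
}

#' @export
print.model_spec <- function(x, ...) {
  cat(sprintf("<model_spec %s/%s> %s\n", x$scale, x$period, x$label))
  invisible(x)
}

# Design matrix for a term vector. Aspect becomes 4 dummies against the
# "north" reference; interactions are products of (already standardised)
# columns. Intercept only when requested (landscape scale).
build_model_matrix <- function(rows, terms, intercept = FALSE) {
  cols <- list()
  if (intercept) cols[["(Intercept)"]] <- rep(1, nrow(rows))
  for (tm in terms) {
    if (tm == "aspect") {
      a <- factor(as.character(rows$aspect),
                  levels = c("north", "east", "south", "west", "flat"))
      if (anyNA(a)) stopf("aspect contains values outside the 5 levels")
      for (lev in levels(a)[-1]) {
        cols[[paste0("aspect_", lev)]] <- as.numeric(a == lev)
      }
    } else if (grepl(":", tm, fixed = TRUE)) {
      pp <- strsplit(tm, ":", fixed = TRUE)[[1]]
      for (p in pp) if (is.null(rows[[p]])) stopf("missing column '%s' for term '%s'", p, tm)
      cols[[tm]] <- rows[[pp[1]]] * rows[[pp[2]]]
    } else {
      if (is.null(rows[[tm]])) stopf("missing column '%s'", tm)
      cols[[tm]] <- rows[[tm]]
    }
  }
  X <- do.call(cbind, cols)
  colnames(X) <- names(cols)
  if (anyNA(X)) stopf("design matrix contains NA values; check covariate attribution")
  X
}
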