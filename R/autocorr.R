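## autocorr: Broto-Moreau (ATS), Moran (MATS) and Geary (GATS) 2D
## autocorrelation descriptors on hydrogen-suppressed molecular graphs.
##
## Conventions (see the methods vignette for the full discussion):
##  * ATS(p_k, l)  = sum over unordered atom pairs {i,j} with d_ij = l of
##    p_ki * p_kj (each pair counted once); 0 when no pair exists.
##  * MATS(p_k, l) = Moran's index:
##    [ (1/2L) sum_ij delta(l,d_ij) (p_ki - pbar)(p_kj - pbar) ] /
##    [ (1/N)  sum_i (p_ki - pbar)^2 ],  double sum over ordered pairs,
##    L = number of unordered pairs at lag l.
##  * GATS(p_k, l) = Geary's coefficient:
##    [ (1/2L) sum_{unordered pairs at lag l} (p_ki - p_kj)^2 ] /
##    [ (1/(N-1)) sum_i (p_ki - pbar)^2 ].
##  MATS and GATS are undefined (NA) when L = 0 or the property variance is
##  zero; `as_printed = TRUE` evaluates the literal journal-style formulas
##  (Moran-type numerator and unsquared deviation denominator for both)
##  for audit purposes.

.autocorr_properties <- c("m", "v", "e", "p")
.autocorr_families <- c("ATS", "MATS", "GATS")

prop_values <- function(g, k) {
  k <- match.arg(k, .autocorr_properties)
  g$props[, k]
}

# Unordered atom pairs at topological lag l, as a 2-column matrix.
lag_pairs <- function(g, l) {
  idx <- which(g$dist == l & upper.tri(g$dist), arr.ind = TRUE)
  idx
}

#' Broto-Moreau autocorrelation ATS(p_k, l)
#'
#' Sum of `p_ki * p_kj` over unordered heavy-atom pairs at topological
#' distance `l`.  Returns 0 when the lag exceeds the graph diameter.
#'
#' @param g a `molecular_graph` from [build_graph()].
#' @param k atomic property: `"m"`, `"v"`, `"e"` or `"p"`.
#' @param l topological lag (>= 1).
#' @return a single number.
#' @export
ats <- function(g, k, l) {
  stopifnot(inherits(g, "molecular_graph"), l >= 1)
  p <- prop_values(g, k)
  pr <- lag_pairs(g, l)
  if (nrow(pr) == 0) return(0)
  sum(p[pr[, 1]] * p[pr[, 2]])
}

#' Moran autocorrelation MATS(p_k, l)
#'
#' Moran's spatial autocorrelation index over the molecular graph at lag
#' `l`, weighted by atomic property `k`.  `NA` (flagged undefined) when no
#' atom pair exists at the lag or the property is constant over the
#' molecule.
#'
#' @inheritParams ats
#' @param as_printed evaluate the literal journal-style formula (no square
#'   on the denominator deviations) instead of the standard Moran form.
#' @return a single number, or `NA_real_` when undefined.
#' @export
mats <- function(g, k, l, as_printed = FALSE) {
  stopifnot(inherits(g, "molecular_graph"), l >= 1)
  p <- prop_values(g, k)
  dev <- p - mean(p)
  pr <- lag_pairs(g, l)
  L <- nrow(pr)
  den <- if (as_printed) sum(dev) else sum(dev^2)
  if (L == 0 || abs(den) < 1e-12) return(NA_real_)
  num <- 2 * sum(dev[pr[, 1]] * dev[pr[, 2]])  # ordered double sum
  (num / (2 * L)) / (den / g$n_atoms)
}

#' Geary autocorrelation GATS(p_k, l)
#'
#' Geary's coefficient over the molecular graph at lag `l`, weighted by
#' atomic property `k`: squared property differences over pairs at the lag
#' against the property variance.  `NA` (flagged undefined) when no pair
#' exists at the lag or the property is constant.
#'
#' @inheritParams mats
#' @param as_printed evaluate the literal journal-style formula
#'   (Moran-style cross-product numerator with an `(N-1)/(4L)` prefactor
#'   and unsquared denominator deviations) instead of the standard Geary
#'   form.
#' @return a single number, or `NA_real_` when undefined.
#' @export
gats <- function(g, k, l, as_printed = FALSE) {
  stopifnot(inherits(g, "molecular_graph"), l >= 1)
  p <- prop_values(g, k)
  dev <- p - mean(p)
  pr <- lag_pairs(g, l)
  L <- nrow(pr)
  if (as_printed) {
    den <- sum(dev)
    if (L == 0 || abs(den) < 1e-12) return(NA_real_)
    num <- 2 * sum(dev[pr[, 1]] * dev[pr[, 2]])
    return((g$n_atoms - 1) / (4 * L) * num / den)
  }
  den <- sum(dev^2)
  if (L == 0 || den < 1e-12) return(NA_real_)
  num <- sum((p[pr[, 1]] - p[pr[, 2]])^2)
  (num / (2 * L)) / (den / (g$n_atoms - 1))
}

#' Parse or render descriptor names
#'
#' Descriptor names follow the `family + lag + property` convention, e.g.
#' `"MATS7e"` is the Moran index at lag 7 weighted by Sanderson
#' electronegativity.
#'
#' @param name character vector of descriptor names.
#' @return `parse_descriptor_name`: data.frame with columns `family`,
#'   `lag`, `property`; `descriptor_name`: character vector.
#' @examples
#' parse_descriptor_name("MATS7e")
#' descriptor_name("GATS", 5, "e")
#' @export
parse_descriptor_name <- function(name) {
  m <- regmatches(name, regexec("^(ATS|MATS|GATS)([1-8])([mvep])$", name))
  bad <- vapply(m, length, integer(1)) != 4L
  if (any(bad)) stop("not a valid descriptor name: ",
                     paste(name[bad], collapse = ", "))
  data.frame(family = vapply(m, `[`, "", 2),
             lag = as.integer(vapply(m, `[`, "", 3)),
             property = vapply(m, `[`, "", 4),
             stringsAsFactors = FALSE)
}

#' @rdname parse_descriptor_name
#' @param family,lag,property descriptor spec fields.
#' @export
descriptor_name <- function(family, lag, property) {
  paste0(family, lag, property)
}

#' Compute the full 96-column 2D autocorrelation block
#'
#' All three families x four atomic properties x lags 1..8 for a list of
#' molecules, in deterministic column order (family, then property, then
#' lag).  Undefined Moran/Geary cells are `NA` (flagged undefined), not
#' zero; the QSAR filter stage treats such columns as uninformative.
#'
#' @param mols a list of `molecular_graph` objects (optionally named), or a
#'   character vector of SMILES.
#' @param lags integer vector of lags (default `1:8`).
#' @param properties atomic properties to weight by (default all four).
#' @param as_printed passed to [mats()]/[gats()].
#' @return numeric matrix, rows = molecules, columns = descriptors, with a
#'   `"descriptor_spec"` attribute holding the per-column provenance.
#' @examples
#' g <- build_graph(read_structure("CCO", format = "smiles"))
#' dim(descriptor_block(list(CCO = g)))  # 1 x 96
#' @export
descriptor_block <- function(mols, lags = 1:8,
                             properties = .autocorr_properties,
                             as_printed = FALSE) {
  if (is.character(mols)) {
    nm <- names(mols) %||% mols
    mols <- lapply(mols, function(s) build_graph(read_structure(s, "smiles")))
    names(mols) <- nm
  }
  stopifnot(length(mols) >= 1, all(vapply(mols, inherits, TRUE, "molecular_graph")))
  spec <- expand.grid(lag = lags, property = properties,
                      family = .autocorr_families,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  spec <- spec[, c("family", "property", "lag")]
  cols <- descriptor_name(spec$family, spec$lag, spec$property)
  out <- matrix(NA_real_, nrow = length(mols), ncol = nrow(spec),
                dimnames = list(names(mols), cols))
  for (i in seq_along(mols)) {
    g <- mols[[i]]
    for (j in seq_len(nrow(spec))) {
      f <- switch(spec$family[j], ATS = ats,
                  MATS = function(...) mats(..., as_printed = as_printed),
                  GATS = function(...) gats(..., as_printed = as_printed))
      out[i, j] <- f(g, spec$property[j], spec$lag[j])
    }
  }
  attr(out, "descriptor_spec") <- spec
  out
}
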