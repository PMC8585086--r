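# JSON persistence of a fitted index. The written file is the versioned
# "index definition": everything needed to score new data without
# refitting, at full double precision so reload reproduces scores
# bit-identically.

#' Save a fitted index as JSON
#'
#' @param object a fitted \code{mcri} object.
#' @param path output file.
#' @return \code{path}, invisibly.
#' @export
write_mcri <- function(object, path) {
  fm <- object$factor_model
  payload <- list(
    package_version = as.character(utils::packageVersion("mcri")),
    items = fm$items,
    factor_names = colnames(fm$loadings),
    loadings = as.data.frame(fm$loadings),
    phi = as.data.frame(fm$phi),
    uniqueness = as.list(fm$uniqueness),
    item_means = as.list(object$item_means),
    item_sds = as.list(object$item_sds),
    bounds100 = object$bounds100,
    composite = list(center = as.list(object$composite$center),
                     scale = as.list(object$composite$scale),
                     weights = as.list(object$composite$weights),
                     eigenvalues = object$composite$eigenvalues,
                     explained = object$composite$explained,
                     range = object$composite$range,
                     n = object$composite$n),
    trail = as.list(object$trail),
    kmo = as.list(object$kmo),
    parallel_analysis = object$parallel_analysis,
    vss = object$vss,
    n_pooled = object$n_pooled,
    n_constructs = object$n_constructs)
  # I(17) significant digits: lossless for IEEE doubles, so reload
  # scores bit-identically
  jsonlite::write_json(payload, path, digits = I(17), auto_unbox = TRUE,
                       pretty = TRUE)
  invisible(path)
}

#' Load a fitted index from JSON
#'
#' @param path file written by \code{\link{write_mcri}}.
#' @return an \code{mcri} object that scores identically to the saved
#'   one.
#' @export
read_mcri <- function(path) {
  p <- jsonlite::fromJSON(path)
  mk <- function(m) {
    m <- as.matrix(m)
    storage.mode(m) <- "double"
    m
  }
  L <- mk(p$loadings)
  dimnames(L) <- list(p$items, p$factor_names)
  phi <- mk(p$phi)
  dimnames(phi) <- list(p$factor_names, p$factor_names)
  fm <- list(loadings = L, phi = phi, structure = L %*% phi,
             communality = 1 - unlist(p$uniqueness),
             uniqueness = unlist(p$uniqueness),
             items = p$items, rotmat = NULL)
  class(fm) <- "factor_model"
  comp <- list(center = unlist(p$composite$center),
               scale = unlist(p$composite$scale),
               weights = unlist(p$composite$weights),
               eigenvalues = p$composite$eigenvalues,
               explained = p$composite$explained,
               range = p$composite$range,
               n = p$composite$n)
  class(comp) <- "composite_model"
  obj <- list(call = NULL, factor_model = fm, composite = comp,
              item_means = unlist(p$item_means),
              item_sds = unlist(p$item_sds),
              bounds100 = lapply(p$bounds100, as.numeric),
              trail = unlist(p$trail),
              subsets = NULL,
              kmo = unlist(p$kmo),
              parallel_analysis = p$parallel_analysis,
              vss = p$vss,
              n_pooled = p$n_pooled, n_constructs = p$n_constructs)
  class(obj) <- "mcri"
  obj
}
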