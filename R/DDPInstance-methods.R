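.asFragments <- function(v, what) {
  if (is.null(v) || length(v) == 0L)
    stop(sprintf("'%s' must contain at least one fragment length", what))
  if (!is.numeric(v))
    stop(sprintf("'%s' must be numeric", what))
  if (any(v != round(v)))
    stop(sprintf("'%s' must contain whole-number fragment lengths", what))
  as.integer(v)
}

#' Construct a double digest problem instance
#'
#' @param a,b,c non-negative integer fragment lengths of the A-digest,
#'   B-digest and double digest respectively.
#' @param name optional instance label.
#' @return A [DDPInstance-class] object. Construction does not require the
#'   three totals to agree; use [validateInstance()] to check.
#' @examples
#' ins <- DDPInstance(c(1, 2, 3, 5), c(2, 2, 3, 4), c(1, 1, 1, 2, 2, 2, 2))
#' validateInstance(ins)
#' @export
DDPInstance <- function(a, b, c, name = "instance") {
  new("DDPInstance", a = .asFragments(a, "a"), b = .asFragments(b, "b"),
      c = .asFragments(c, "c"), name = as.character(name)[1L])
}

#' Accessors for DDPInstance
#'
#' \code{fragmentsA}, \code{fragmentsB}, \code{fragmentsC} return the three
#' fragment-length vectors; \code{instanceName} the label; \code{totalLength}
#' the common total length L for a valid instance (NA with a warning for an
#' invalid one).
#'
#' @param x a [DDPInstance-class].
#' @name DDPInstance-accessors
#' @aliases fragmentsA fragmentsB fragmentsC instanceName totalLength
NULL

#' @rdname DDPInstance-accessors
#' @export
setMethod("fragmentsA", "DDPInstance", function(x) x@a)

#' @rdname DDPInstance-accessors
#' @export
setMethod("fragmentsB", "DDPInstance", function(x) x@b)

#' @rdname DDPInstance-accessors
#' @export
setMethod("fragmentsC", "DDPInstance", function(x) x@c)

#' @rdname DDPInstance-accessors
#' @export
setMethod("instanceName", "DDPInstance", function(x) x@name)

#' @rdname DDPInstance-accessors
#' @export
setMethod("totalLength", "DDPInstance", function(x) {
  s <- c(sum(x@a), sum(x@b), sum(x@c))
  if (length(unique(s)) != 1L) {
    warning("instance is invalid (unequal totals); totalLength is NA")
    return(NA_integer_)
  }
  s[1L]
})

#' Check the equal-totals restriction of a DDP instance
#'
#' A DDP instance is solvable only if the three digests account for the same
#' molecule, i.e. sum(a) = sum(b) = sum(c). This reports the three sums and
#' the verdict without raising, so that defective instances can be loaded
#' and diagnosed.
#'
#' @param x a [DDPInstance-class].
#' @return A list with elements \code{valid} (logical), \code{sums} (named
#'   integer vector of the three totals) and \code{message}.
#' @examples
#' validateInstance(DDPInstance(c(5, 6, 6, 7, 7, 17),
#'                              c(3, 5, 6, 6, 7, 21),
#'                              c(1, 2, 2, 3, 3, 3, 4, 4, 5, 5, 16)))
#' @rdname validateInstance
#' @export
setMethod("validateInstance", "DDPInstance", function(x) {
  s <- c(a = sum(x@a), b = sum(x@b), c = sum(x@c))
  valid <- length(unique(s)) == 1L
  msg <- if (valid) {
    sprintf("valid: common total length %d", s[["a"]])
  } else {
    sprintf("invalid: sum(a) = %d, sum(b) = %d, sum(c) = %d differ",
            s[["a"]], s[["b"]], s[["c"]])
  }
  list(valid = valid, sums = s, message = msg)
})

#' @rdname validateInstance
#' @export
isValidInstance <- function(x) validateInstance(x)$valid

#' Is an instance in canonical form (k = m + n - 1)?
#' @param x a [DDPInstance-class].
#' @return logical.
#' @export
isCanonical <- function(x) {
  length(x@c) == length(x@a) + length(x@b) - 1L
}

#' Pad an instance with zero-length fragments to canonical form
#'
#' When the two enzymes cut at disjoint sites the double digest has exactly
#' k = m + n - 1 fragments. Coincident cut sites (or measurement dropouts)
#' break this, so delta = (m + n - 1) - k zero-length fragments are appended
#' to \code{c}; in the opposite direction (k too large) zeros are appended
#' to the shorter of \code{a} and \code{b} (to \code{a} on ties). Totals are
#' unchanged, and the zero-length fragments reappear explicitly in rendered
#' maps.
#'
#' @param x a *valid* [DDPInstance-class].
#' @return A canonical [DDPInstance-class] with k = m + n - 1.
#' @examples
#' padded <- padToCanonical(DDPInstance(c(1, 1), c(1, 1), c(1, 1)))
#' fragmentsC(padded)  # 1 1 0
#' @rdname padToCanonical
#' @export
setMethod("padToCanonical", "DDPInstance", function(x) {
  rep_ <- validateInstance(x)
  if (!rep_$valid)
    stop("cannot pad an invalid instance: ", rep_$message)
  m <- length(x@a); n <- length(x@b); k <- length(x@c)
  delta <- (m + n - 1L) - k
  while (delta > 0L) {             # too few double-digest fragments
    x@c <- c(x@c, integer(delta))
    delta <- 0L
  }
  while (delta < 0L) {             # k exceeds m + n - 1: grow a or b
    if (length(x@a) <= length(x@b)) x@a <- c(x@a, 0L) else x@b <- c(x@b, 0L)
    delta <- delta + 1L
  }
  x
})

setMethod("show", "DDPInstance", function(object) {
  rep_ <- validateInstance(object)
  cat(sprintf("DDPInstance \"%s\" (m = %d, n = %d, k = %d)\n", object@name,
              length(object@a), length(object@b), length(object@c)))
  cat("  a:", paste(object@a, collapse = " "), "\n")
  cat("  b:", paste(object@b, collapse = " "), "\n")
  cat("  c:", paste(object@c, collapse = " "), "\n")
  cat(" ", rep_$message, "\n")
  invisible(object)
})
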