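#' Country / region / super-region hierarchy
#'
#' The model nests countries in regions, regions in super-regions, and
#' super-regions in the globe. A hierarchy_spec holds the two membership maps.
#'
#' @param region_of integer vector of length J, region index (1..L) of each
#'   country.
#' @param sregion_of integer vector of length L, super-region index (1..M) of
#'   each region.
#' @return An object of class "hierarchy_spec" with elements J, L, M,
#'   region_of, sregion_of and the composed country -> super-region map
#'   sregion_of_country.
#' @examples
#' h <- hierarchy_spec(region_of = c(1, 1, 2, 2), sregion_of = c(1, 1))
#' @export
hierarchy_spec <- function(region_of, sregion_of) {
  region_of <- as.integer(region_of)
  sregion_of <- as.integer(sregion_of)
  J <- length(region_of); L <- length(sregion_of)
  if (J < 1L || L < 1L) stop("hierarchy must have at least one country and one region")
  if (any(is.na(region_of)) || any(region_of < 1L) || any(region_of > L))
    stop("region_of must map every country to a region in 1..L")
  M <- max(sregion_of)
  if (any(is.na(sregion_of)) || any(sregion_of < 1L))
    stop("sregion_of must map every region to a super-region")
  if (!setequal(unique(sregion_of), seq_len(M)))
    stop("super-region indices must be 1..M with no gaps")
  if (!setequal(unique(region_of), seq_len(L)))
    stop("region indices must be 1..L with no gaps")
  if (!(J >= L && L >= M)) stop("hierarchy requires J >= L >= M")
  structure(list(J = J, L = L, M = M,
                 region_of = region_of, sregion_of = sregion_of,
                 sregion_of_country = sregion_of[region_of]),
            class = "hierarchy_spec")
}

#' @export
print.hierarchy_spec <- function(x, ...) {
  cat(sprintf("hierarchy_spec: %d countries in %d regions in %d super-regions\n",
              x$J, x$L, x$M))
  invisible(x)
}

# Balanced default hierarchy used by the synthetic-data generator.
balanced_hierarchy <- function(J, L, M) {
  hierarchy_spec(region_of = sort(rep(seq_len(L), length.out = J)),
                 sregion_of = sort(rep(seq_len(M), length.out = L)))
}
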