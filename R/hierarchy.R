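#' Build a synthetic country hierarchy
#'
#' Assigns countries to regions and regions to super-regions as evenly as
#' possible, with the assignment randomised by `seed`. Mirrors the nesting
#' used for partial pooling: country within region within super-region
#' within world.
#'
#' @param n_countries,n_regions,n_super_regions Sizes of each level; must
#'   satisfy `n_countries >= n_regions >= n_super_regions >= 1`.
#' @param seed Integer seed; the same seed reproduces the same hierarchy.
#' @return A `country_index` object: list with `countries`, `regions`,
#'   `super_regions` (codes), `region_of` (named character, country ->
#'   region) and `super_region_of` (region -> super-region).
#' @export
#' @examples
#' h <- make_hierarchy(6, 3, 2, seed = 1)
#' h$region_of
make_hierarchy <- function(n_countries, n_regions, n_super_regions, seed = 1) {
  if (!(n_countries >= n_regions && n_regions >= n_super_regions &&
        n_super_regions >= 1)) {
    stop("need n_countries >= n_regions >= n_super_regions >= 1")
  }
  countries <- sprintf("C%03d", seq_len(n_countries))
  regions <- sprintf("R%02d", seq_len(n_regions))
  supers <- sprintf("S%d", seq_len(n_super_regions))

  balanced_assign <- function(items, groups, rng_perm) {
    # round-robin over a seeded permutation keeps group sizes within 1
    reps <- rep(groups, length.out = length(items))
    stats::setNames(reps, items[rng_perm])
  }
  assigned <- with_seed(seed, {
    list(region_of = balanced_assign(countries, regions,
                                     sample.int(n_countries)),
         super_region_of = balanced_assign(regions, supers,
                                           sample.int(n_regions)))
  })
  region_of <- assigned$region_of[order(names(assigned$region_of))]
  super_region_of <-
    assigned$super_region_of[order(names(assigned$super_region_of))]

  structure(list(countries = countries, regions = regions,
                 super_regions = supers, region_of = region_of,
                 super_region_of = super_region_of),
            class = "country_index")
}

#' Validate a country hierarchy
#'
#' Checks that every country maps to exactly one region and every region to
#' exactly one super-region.
#'
#' @param hierarchy A `country_index`.
#' @return The input, invisibly.
#' @export
validate_hierarchy <- function(hierarchy) {
  h <- hierarchy
  stopifnot(inherits(h, "country_index"))
  if (!setequal(names(h$region_of), h$countries) ||
      anyNA(h$region_of) || !all(h$region_of %in% h$regions)) {
    stop("every country must map to exactly one region")
  }
  if (!setequal(names(h$super_region_of), h$regions) ||
      anyNA(h$super_region_of) || !all(h$super_region_of %in% h$super_regions)) {
    stop("every region must map to exactly one super-region")
  }
  invisible(h)
}

#' @export
print.country_index <- function(x, ...) {
  cat(sprintf("country hierarchy: %d countries, %d regions, %d super-regions\n",
              length(x$countries), length(x$regions), length(x$super_regions)))
  invisible(x)
}

# Integer index maps used by the sampler: country -> region index, etc.
hierarchy_indices <- function(hierarchy) {
  h <- validate_hierarchy(hierarchy)
  r_of_c <- match(h$region_of[h$countries], h$regions)
  s_of_r <- match(h$super_region_of[h$regions], h$super_regions)
  list(nC = length(h$countries), nR = length(h$regions),
       nS = length(h$super_regions),
       region_of_country = r_of_c, super_of_region = s_of_r,
       super_of_country = s_of_r[r_of_c])
}
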