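#' Livestock category registry
#'
#' The inventory covers 12 livestock categories. Ruminants are dairy
#' cattle, nondairy cattle, buffalo, sheep, goats and camels; the rest are
#' nonruminants. Categories with region-specific Tier 2 emission-factor
#' pathways are dairy cattle (milk regression), nondairy cattle, buffalo,
#' sheep, goats (gross-energy model) and swine (volatile-solids manure
#' pathway, constant enteric factor). Minor species (horse, donkey, mule,
#' poultry, rabbit, camel) use fixed Tier 1 factor pairs.
#'
#' @return A `data.table` with columns `category`, `tier`
#'   (`"tier1"`/`"tier2"`) and `ruminant` (logical), one row per category.
#' @export
#' @examples
#' livestock_categories()
livestock_categories <- function() {
  data.table(
    category = c("dairy_cattle", "nondairy_cattle", "buffalo", "sheep",
                 "goat", "swine", "camel", "horse", "donkey", "mule",
                 "poultry", "rabbit"),
    tier     = c(rep("tier2", 6L), rep("tier1", 6L)),
    ruminant = c(TRUE, TRUE, TRUE, TRUE, TRUE, FALSE,
                 TRUE, FALSE, FALSE, FALSE, FALSE, FALSE)
  )
}

#' Subclasses admitted by a livestock category
#'
#' Cattle and buffalo are split into mature females, young animals and
#' others; sheep and goats into mature females and others; all remaining
#' categories are treated as a whole herd.
#'
#' @param category Character vector of category codes.
#' @return For `subclasses_of()`, a character vector of subclass codes for
#'   a single category; for `subclass_table()`, a `data.table` of all
#'   (category, subclass) pairs.
#' @export
#' @examples
#' subclasses_of("nondairy_cattle")
#' subclasses_of("swine")
subclasses_of <- function(category) {
  stopifnot(length(category) == 1L)
  assert_category(category)
  if (category %in% c("dairy_cattle", "nondairy_cattle", "buffalo")) {
    c("mature_female", "young", "other")
  } else if (category %in% c("sheep", "goat")) {
    c("mature_female", "other")
  } else {
    "whole_herd"
  }
}

#' @rdname subclasses_of
#' @export
subclass_table <- function() {
  cats <- livestock_categories()$category
  rbindlist(lapply(cats, function(cc)
    data.table(category = cc, subclass = subclasses_of(cc))))
}

CATEGORY_CODES <- c("dairy_cattle", "nondairy_cattle", "buffalo", "sheep",
                    "goat", "swine", "camel", "horse", "donkey", "mule",
                    "poultry", "rabbit")
SUBCLASS_CODES <- c("mature_female", "young", "other", "whole_herd")
PATHWAYS       <- c("enteric", "manure")
MGMT_SYSTEMS   <- c("pasture", "daily_spread", "solid_storage", "dry_lot",
                    "liquid_slurry", "anaerobic_digester", "lagoon", "other")
CLIMATE_CLASSES <- c("cool", "temperate", "warm")

assert_category <- function(x) {
  bad <- setdiff(unique(x), CATEGORY_CODES)
  if (length(bad))
    stop("unknown livestock category: ", paste(bad, collapse = ", "),
         call. = FALSE)
  invisible(x)
}

is_tier2 <- function(category) {
  category %in% c("dairy_cattle", "nondairy_cattle", "buffalo", "sheep",
                  "goat", "swine")
}

is_ruminant <- function(category) {
  category %in% c("dairy_cattle", "nondairy_cattle", "buffalo", "sheep",
                  "goat", "camel")
}
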