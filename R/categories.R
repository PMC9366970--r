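#' Category map: raw establishment categories to broad types
#'
#' A `category_map` partitions raw category strings (Google-Places-style or
#' NETS industry descriptions) into a small number of broad "types" used for
#' the commercial-activity-diversity measure. Lookups are case- and
#' whitespace-insensitive.
#'
#' @param entries either a named character vector (names = raw categories,
#'   values = broad type) or a data frame with columns `raw` and `type`.
#' @param type_names optional character vector fixing the order/universe of
#'   broad types; defaults to the distinct mapped types in `entries`.
#' @return a `category_map` object.
#' @seealso [default_category_map()], [read_category_map()], [map_category()]
#' @export
category_map <- function(entries, type_names = NULL) {
  if (is.data.frame(entries)) {
    if (!all(c("raw", "type") %in% names(entries))) {
      pa_stop_structural("category map data frame needs columns 'raw' and 'type'")
    }
    v <- as.character(entries$type)
    names(v) <- as.character(entries$raw)
    entries <- v
  }
  if (!is.character(entries) || is.null(names(entries)) || length(entries) == 0L) {
    pa_stop_structural("category map entries must be a non-empty named character vector")
  }
  raw <- normalize_category(names(entries))
  if (anyDuplicated(raw)) {
    dup <- raw[duplicated(raw)][1L]
    pa_stop_structural(sprintf("raw category '%s' mapped more than once", dup))
  }
  names(entries) <- raw
  type_names <- type_names %||% unique(unname(entries))
  if (!all(entries %in% type_names)) {
    pa_stop_structural("entries map to types outside 'type_names'")
  }
  structure(list(entries = entries, type_names = type_names),
            class = "category_map")
}

normalize_category <- function(x) {
  tolower(trimws(gsub("[[:space:]]+", " ", as.character(x))))
}

#' @export
print.category_map <- function(x, ...) {
  cat(sprintf("<category_map: %d raw categories -> %d types>\n",
              length(x$entries), length(x$type_names)))
  invisible(x)
}

#' Default broad-type category map
#'
#' A shipped mapping of common Google-Places-style raw categories into 15
#' broad types (restaurant, cafe, bar, grocery, retail/services,
#' health/medical, education, finance, lodging, transit, recreation/fitness,
#' culture, religious, government/civic, other). The exact partition used in
#' any given study is replaceable via [read_category_map()]; the diversity
#' statistic only requires a consistent partition.
#'
#' @return a [category_map()] with 15 types.
#' @export
default_category_map <- function() {
  category_map(default_map_entries, type_names = default_type_names)
}

default_type_names <- c(
  "Restaurant", "Cafe", "Bar", "Grocery", "Retail/services",
  "Health/medical", "Education", "Finance", "Lodging", "Transit",
  "Recreation/fitness", "Culture", "Religious", "Government/civic", "Other"
)

default_map_entries <- c(
  # food & drink
  "restaurant" = "Restaurant", "meal takeaway" = "Restaurant",
  "meal delivery" = "Restaurant", "pizza restaurant" = "Restaurant",
  "fast food restaurant" = "Restaurant", "bakery" = "Cafe",
  "cafe" = "Cafe", "coffee shop" = "Cafe",
  "bar" = "Bar", "night club" = "Bar", "pub" = "Bar", "liquor store" = "Bar",
  # daily needs
  "grocery or supermarket" = "Grocery", "supermarket" = "Grocery",
  "convenience store" = "Grocery", "grocery store" = "Grocery",
  # retail & services (paper's worked example of the grouping)
  "clothing store" = "Retail/services", "shoe store" = "Retail/services",
  "department store" = "Retail/services", "hardware store" = "Retail/services",
  "electronics store" = "Retail/services", "furniture store" = "Retail/services",
  "beauty salon" = "Retail/services", "hair care" = "Retail/services",
  "laundry" = "Retail/services", "florist" = "Retail/services",
  "pet store" = "Retail/services", "book store" = "Retail/services",
  "jewelry store" = "Retail/services", "store" = "Retail/services",
  "shopping mall" = "Retail/services", "car repair" = "Retail/services",
  # health
  "hospital" = "Health/medical", "doctor" = "Health/medical",
  "dentist" = "Health/medical", "pharmacy" = "Health/medical",
  "physiotherapist" = "Health/medical", "veterinary care" = "Health/medical",
  # education
  "school" = "Education", "primary school" = "Education",
  "secondary school" = "Education", "university" = "Education",
  "library" = "Education",
  # finance
  "bank" = "Finance", "atm" = "Finance", "accounting" = "Finance",
  "insurance agency" = "Finance", "real estate agency" = "Finance",
  # lodging
  "lodging" = "Lodging", "hotel" = "Lodging",
  # transit
  "transit station" = "Transit", "subway station" = "Transit",
  "bus station" = "Transit", "train station" = "Transit",
  "taxi stand" = "Transit", "parking" = "Transit", "gas station" = "Transit",
  # recreation
  "gym" = "Recreation/fitness", "stadium" = "Recreation/fitness",
  "bowling alley" = "Recreation/fitness", "amusement park" = "Recreation/fitness",
  "spa" = "Recreation/fitness",
  # culture
  "museum" = "Culture", "art gallery" = "Culture",
  "movie theater" = "Culture", "tourist attraction" = "Culture",
  # religious
  "church" = "Religious", "mosque" = "Religious", "synagogue" = "Religious",
  "hindu temple" = "Religious", "place of worship" = "Religious",
  # civic
  "city hall" = "Government/civic", "local government office" = "Government/civic",
  "post office" = "Government/civic", "courthouse" = "Government/civic",
  "police" = "Government/civic", "fire station" = "Government/civic",
  "embassy" = "Government/civic",
  # catch-all examples
  "point of interest" = "Other", "establishment" = "Other"
)

#' Read a category map from CSV
#'
#' @param path CSV file with columns `raw` and `type`.
#' @param type_names optional universe of types, as in [category_map()].
#' @return a [category_map()].
#' @export
read_category_map <- function(path, type_names = NULL) {
  if (!file.exists(path)) {
    pa_stop_structural(sprintf("category map file not found: %s", path))
  }
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  category_map(df, type_names = type_names)
}

#' Map a raw category to its broad type
#'
#' @param raw character vector of raw category strings.
#' @param cmap a [category_map()]; defaults to [default_category_map()].
#' @param unmapped policy for raw categories absent from the map: `"error"`
#'   (strict) or `"other"` (lenient; assigned to `other_type`).
#' @param other_type type name used by the lenient policy (default "Other").
#' @return character vector of broad type names, same length as `raw`.
#' @export
map_category <- function(raw, cmap = default_category_map(),
                         unmapped = c("error", "other"),
                         other_type = "Other") {
  unmapped <- match.arg(unmapped)
  if (!inherits(cmap, "category_map") || length(cmap$entries) == 0L) {
    pa_stop_structural("'cmap' must be a non-empty category_map")
  }
  key <- normalize_category(raw)
  out <- unname(cmap$entries[key])
  miss <- is.na(out)
  if (any(miss)) {
    if (unmapped == "error") {
      pa_stop_structural(sprintf(
        "unmapped raw category: '%s'", raw[miss][1L]
      ))
    }
    out[miss] <- other_type
  }
  out
}

#' Primary category of an establishment
#'
#' Establishments carry an ordered list of raw categories; the first entry
#' is taken as the category used for type mapping.
#'
#' @param raw_list non-empty character vector (or list) of raw categories,
#'   most specific first.
#' @return the first category string.
#' @export
primary_category <- function(raw_list) {
  raw_list <- unlist(raw_list, use.names = FALSE)
  if (length(raw_list) == 0L) {
    pa_stop_structural("establishment category list is empty")
  }
  as.character(raw_list[[1L]])
}

#' Commercial activity diversity: number of distinct broad types
#'
#' Counts the distinct broad establishment types represented in a set of
#' establishments (typically those within one park buffer).
#'
#' @param establishments a data frame with a `type` column, or (if `type` is
#'   absent) a `raw_category` column mapped through `cmap`; alternatively a
#'   plain character vector of types.
#' @param cmap a [category_map()] used when raw categories must be mapped.
#' @param unmapped unmapped-category policy passed to [map_category()].
#' @return non-negative integer count of distinct types (0 for empty input).
#' @export
count_types <- function(establishments, cmap = default_category_map(),
                        unmapped = c("error", "other")) {
  unmapped <- match.arg(unmapped)
  if (is.character(establishments)) {
    types <- establishments
  } else if (is.data.frame(establishments)) {
    if (nrow(establishments) == 0L) return(0L)
    if (!is.null(establishments$type)) {
      types <- establishments$type
    } else if (!is.null(establishments$raw_category)) {
      types <- map_category(establishments$raw_category, cmap, unmapped)
    } else {
      pa_stop_structural("establishments need a 'type' or 'raw_category' column")
    }
  } else {
    pa_stop_structural("'establishments' must be a data frame or character vector")
  }
  types <- types[!is.na(types)]
  length(unique(types))
}
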