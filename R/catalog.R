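#' Canonical app-category names
#'
#' The closed set of 27 store-style app categories used by the marker grid.
#' Category names are case-stable and use spaces internally; feature names
#' replace spaces with underscores.
#'
#' @return Character vector of length 27.
#' @export
app_categories <- function() {
  c("Art and Design", "Auto and Vehicles", "Beauty", "Books and Reference",
    "Business", "Communication", "Dating", "Education", "Entertainment",
    "Finance", "Food and Drink", "Games", "Health and Fitness",
    "House and Home", "Lifestyle", "Maps and Navigation", "Medical",
    "Music and Audio", "News and Magazines", "Personalization",
    "Photo and Video", "Productivity", "Shopping", "Social", "Sports",
    "Tools", "Weather")
}

#' Build an app catalog from package-to-category pairs
#'
#' @param package Character vector of app package names.
#' @param category Character vector of category names; each must be one of
#'   [app_categories()].
#' @param fallback_category Category returned by [categorize()] for packages
#'   absent from the catalog. Defaults to "Tools" (the most populous store
#'   category).
#' @return An `app_catalog` object (named character vector with attributes).
#' @export
app_catalog <- function(package, category, fallback_category = "Tools") {
  stopifnot(length(package) == length(category))
  if (anyNA(package) || any(!nzchar(package)))
    stop("catalog packages must be non-empty strings")
  bad <- setdiff(unique(category), app_categories())
  if (length(bad))
    stop("unknown app categories: ", paste(bad, collapse = ", "))
  if (!fallback_category %in% app_categories())
    stop("fallback_category must be one of app_categories()")
  dup <- duplicated(package)
  if (any(dup)) {
    # duplicates are tolerated only when they agree
    agg <- tapply(category, package, function(x) length(unique(x)))
    if (any(agg > 1L))
      stop("conflicting categories for package(s): ",
           paste(names(agg)[agg > 1L], collapse = ", "))
    keep <- !dup
    package <- package[keep]; category <- category[keep]
  }
  map <- stats::setNames(category, package)
  structure(map, class = "app_catalog", fallback = fallback_category)
}

#' Read an app catalog from CSV
#'
#' Expects columns `package,category`. Duplicate rows must agree on the
#' category; conflicting duplicates are a load-time error.
#'
#' @param path CSV file path.
#' @inheritParams app_catalog
#' @return An `app_catalog`.
#' @export
read_catalog <- function(path, fallback_category = "Tools") {
  stopifnot(file.exists(path))
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("package", "category")
  if (!all(need %in% names(df)))
    stop("catalog is missing column(s): ",
         paste(setdiff(need, names(df)), collapse = ", "))
  app_catalog(df$package, df$category, fallback_category)
}

#' Map packages to categories
#'
#' Unknown packages fall back to the catalog's fallback category so that
#' every usage interval stays categorized.
#'
#' @param package Character vector of package names.
#' @param catalog An `app_catalog`.
#' @return Character vector of categories, same length as `package`.
#' @export
categorize <- function(package, catalog) {
  stopifnot(inherits(catalog, "app_catalog"))
  out <- unclass(catalog)[package]
  out[is.na(out)] <- attr(catalog, "fallback")
  unname(out)
}
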