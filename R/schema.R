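#' Feature schema for a fuzzy rule network
#'
#' Declares the ordered model features: continuous features are encoded into
#' the three fuzzy concepts low/medium/high; categorical features contribute
#' one indicator slot per level (a binary comorbidity uses the two levels
#' \code{absent}/\code{present}) and need no membership functions.
#'
#' @param names character vector of unique feature names.
#' @param kinds character vector, each \code{"continuous"} or
#'   \code{"categorical"}.
#' @param n_levels integer vector of level counts for categorical features
#'   (ignored, and recorded as NA, for continuous ones); must be >= 2.
#' @param units optional character vector of unit labels (e.g. "mmHg") used
#'   in reports; defaults to "".
#' @return an object of class \code{fz_schema} with elements \code{features}
#'   (a data.frame), \code{n_features}, \code{max_concepts} and
#'   \code{concept_names}.
#' @examples
#' feature_schema(c("sbp", "lvef", "diabetes"),
#'                c("continuous", "continuous", "categorical"),
#'                n_levels = c(NA, NA, 2))
#' @export
feature_schema <- function(names, kinds, n_levels = NULL, units = NULL) {
  stopifnot(length(names) >= 1L, !anyDuplicated(names),
            length(kinds) == length(names))
  kinds <- match.arg(kinds, c("continuous", "categorical"),
                     several.ok = TRUE)
  if (is.null(n_levels)) n_levels <- rep(NA_integer_, length(names))
  stopifnot(length(n_levels) == length(names))
  n_levels <- as.integer(n_levels)
  if (is.null(units)) units <- rep("", length(names))
  cat_idx <- kinds == "categorical"
  if (any(cat_idx & (is.na(n_levels) | n_levels < 2L))) {
    stop("categorical features require n_levels >= 2")
  }
  n_levels[!cat_idx] <- NA_integer_
  n_concepts <- ifelse(cat_idx, n_levels, 3L)
  structure(list(
    features = data.frame(
      name = names, kind = kinds, n_levels = n_levels,
      n_concepts = as.integer(n_concepts), unit = units,
      stringsAsFactors = FALSE
    ),
    n_features = length(names),
    max_concepts = max(n_concepts),
    concept_names = c("low", "medium", "high")
  ), class = "fz_schema")
}

#' @export
print.fz_schema <- function(x, ...) {
  cat("Feature schema:", x$n_features, "features,",
      sum(x$features$kind == "continuous"), "continuous /",
      sum(x$features$kind == "categorical"), "categorical\n")
  print(x$features, row.names = FALSE)
  invisible(x)
}

schema_index <- function(schema, name) {
  i <- match(name, schema$features$name)
  if (anyNA(i)) {
    stop("unknown feature(s): ", paste(name[is.na(i)], collapse = ", "))
  }
  i
}

# Concept labels used for feature i (low/medium/high, or level names).
concept_labels <- function(schema, i) {
  f <- schema$features[i, ]
  if (f$kind == "continuous") return(c("low", "medium", "high"))
  if (f$n_levels == 2L) return(c("absent", "present"))
  paste0("level", seq_len(f$n_levels))
}

# Map a concept label to its slot index for feature i.
concept_slot <- function(schema, i, concept) {
  labs <- concept_labels(schema, i)
  d <- match(concept, labs)
  if (is.na(d)) {
    stop("feature '", schema$features$name[i], "' has no concept '", concept,
         "' (valid: ", paste(labs, collapse = ", "), ")")
  }
  d
}

# N x D logical mask of structurally valid concept slots.
concept_mask <- function(schema) {
  N <- schema$n_features; D <- schema$max_concepts
  mask <- matrix(FALSE, N, D)
  for (i in seq_len(N)) mask[i, seq_len(schema$features$n_concepts[i])] <- TRUE
  mask
}
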