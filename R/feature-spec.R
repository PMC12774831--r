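#' Read a feature specification from YAML
#'
#' The spec declares base annotations (name, type, categories, imputation
#' default, optional missingness indicator) and combination rules pairing a
#' categorical base with a numeric base. The shipped 691-column layout is at
#' \code{system.file("extdata", "feature_spec_691.yaml", package =
#' "snvimpact")}.
#'
#' @param path YAML file
#' @return a \linkS4class{FeatureSpec}
#' @export
readFeatureSpec <- function(path) {
  y <- yaml::read_yaml(path)
  featureSpec(bases = y$features, combos = y$combinations %||% list())
}

#' @rdname readFeatureSpec
#' @param bases list of base declarations
#' @param combos list of combination rules
#' @export
featureSpec <- function(bases, combos = list()) {
  norm <- lapply(bases, function(b) {
    list(name = b$name, type = b$type,
         categories = as.character(b$categories %||% character()),
         default = b$default %||% (if (b$type == "numeric") 0 else NA),
         other = b$other %||% NA_character_,
         combo_label = b$combo_label %||% "full",
         missing_indicator = isTRUE(b$missing_indicator))
  })
  combos <- lapply(combos, function(cmb)
    list(categorical = cmb$categorical, numeric = cmb$numeric))
  spec <- new("FeatureSpec", bases = norm, combos = combos, checksum = "")
  spec@checksum <- spec_checksum(norm, combos)
  validObject(spec)
  spec
}

#' @rdname readFeatureSpec
#' @param spec a \linkS4class{FeatureSpec}
#' @export
writeFeatureSpec <- function(spec, path) {
  strip <- function(b) Filter(function(x)
    !(is.null(x) || (length(x) == 1L && is.na(x)) ||
        identical(x, FALSE) || identical(x, "full") ||
        identical(x, character())), b)
  yaml::write_yaml(list(features = lapply(spec@bases, strip),
                        combinations = spec@combos), path)
  invisible(path)
}

spec_checksum <- function(bases, combos) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(jsonlite::toJSON(list(b = bases, c = combos),
                              auto_unbox = TRUE, null = "null"), tmp)
  unname(tools::md5sum(tmp))
}

spec_base <- function(spec, name) {
  for (b in spec@bases) if (b$name == name) return(b)
  stop("no base annotation named '", name, "'")
}

combo_colnames <- function(spec, cmb) {
  cb <- spec_base(spec, cmb$categorical)
  if (cb$combo_label == "category")
    paste0(cb$categories, "_", cmb$numeric)
  else
    paste0(cb$name, "_", cb$categories, "_", cmb$numeric)
}

#' Expanded column names of a feature spec
#'
#' The expansion count is a pure function of the spec: categoricals one-hot
#' over their categories, numerics and indicators one column each (plus a
#' missingness indicator when declared), combinations one column per
#' category of their categorical base.
#'
#' @param spec a \linkS4class{FeatureSpec}
#' @param what "all", "base" or "combo"
#' @return character vector of column names, in spec order
#' @export
expandedColumnNames <- function(spec, what = c("all", "base", "combo")) {
  what <- match.arg(what)
  base_cols <- unlist(lapply(spec@bases, function(b) {
    cols <- if (b$type == "categorical") paste0(b$name, "_", b$categories)
            else b$name
    if (b$missing_indicator) cols <- c(cols, paste0(b$name, "_missing"))
    cols
  }))
  combo_cols <- unlist(lapply(spec@combos, function(cmb)
    combo_colnames(spec, cmb)))
  out <- switch(what, base = base_cols, combo = combo_cols,
                all = c(base_cols, combo_cols %||% character()))
  if (anyDuplicated(out))
    stop("expanded column names are not unique: ",
         paste(unique(out[duplicated(out)]), collapse = ", "))
  out %||% character()
}

# impute + encode one base annotation into its column block
expand_base <- function(b, values, n) {
  if (is.null(values)) values <- rep(NA, n)
  miss <- is.na(values)
  if (b$type == "categorical") {
    v <- as.character(values)
    if (any(miss)) {
      # no declared default: missing rows one-hot encode as all-zero
      # (e.g. oAA/nAA outside coding sequence)
      v[miss] <- if (!is.null(b$default) && !is.na(b$default))
        as.character(b$default) else "__missing__"
    }
    unknown <- !(v %in% c(b$categories, "__missing__"))
    if (any(unknown)) {
      if (!is.na(b$other) && b$other %in% b$categories) {
        warning(sum(unknown), " unknown '", b$name,
                "' value(s) mapped to '", b$other, "'", call. = FALSE)
        v[unknown] <- b$other
      } else {
        warning(sum(unknown), " unknown '", b$name,
                "' value(s) encoded as all-zero", call. = FALSE)
      }
    }
    block <- matrix(as.numeric(outer(v, b$categories, "==")), nrow = n,
                    dimnames = list(NULL, paste0(b$name, "_", b$categories)))
  } else {
    v <- suppressWarnings(as.numeric(values))
    v[miss] <- as.numeric(b$default)
    block <- matrix(v, ncol = 1, dimnames = list(NULL, b$name))
  }
  if (b$missing_indicator) {
    block <- cbind(block, as.numeric(miss))
    colnames(block)[ncol(block)] <- paste0(b$name, "_missing")
  }
  block
}

#' Expand annotated variants into the combinatorial feature matrix
#'
#' Categorical bases are one-hot encoded, indicator bases 0/1, missing
#' values replaced by each base's declared default (with a 0/1 missingness
#' column when declared). A combination rule (categorical c, numeric v)
#' emits one column per category k with value indicator(c = k) * v. Column
#' order is spec order. Annotation columns absent from the input are
#' treated as all-missing.
#'
#' @param annotated data.frame from \code{\link{annotateVariants}}
#' @param spec a \linkS4class{FeatureSpec}
#' @return an unscaled \linkS4class{FeatureMatrix}
#' @export
expandFeatures <- function(annotated, spec) {
  n <- nrow(annotated)
  blocks <- list()
  for (b in spec@bases)
    blocks[[b$name]] <- expand_base(b, annotated[[b$name]], n)
  base_mat <- do.call(cbind, unname(blocks))
  combo_mats <- lapply(spec@combos, function(cmb) {
    cb <- spec_base(spec, cmb$categorical)
    cat_block <- blocks[[cmb$categorical]][, paste0(cb$name, "_",
                                                    cb$categories),
                                           drop = FALSE]
    num_col <- blocks[[cmb$numeric]][, cmb$numeric]
    m <- cat_block * num_col
    colnames(m) <- combo_colnames(spec, cmb)
    m
  })
  mat <- do.call(cbind, c(list(base_mat), combo_mats))
  stopifnot(identical(colnames(mat), expandedColumnNames(spec)))
  new("FeatureMatrix", mat = mat, scaled = FALSE, checksum = spec@checksum)
}

#' Fit the per-feature standard-deviation scaler on training rows
#'
#' Population (n-denominator) standard deviation per column; constant
#' columns are recorded and dropped from the model's view.
#'
#' @param fm an unscaled \linkS4class{FeatureMatrix} restricted to training
#'   rows
#' @return a \linkS4class{ScalingParams}
#' @export
fitScaler <- function(fm) {
  stopifnot(is(fm, "FeatureMatrix"))
  if (fm@scaled) stop("scaler must be fitted on unscaled features")
  if (nrow(fm@mat) < 2L) stop("need at least 2 rows to fit the scaler")
  sds <- apply(fm@mat, 2L, pop_sd)
  dropped <- names(sds)[sds == 0]
  new("ScalingParams", sds = sds[sds > 0], dropped = dropped)
}

#' Scale features by the training standard deviations
#'
#' Divides every retained column by its training SD (no centering). New
#' variants are scaled with the training SDs, never their own. Applying a
#' scaler to an already-scaled matrix is refused.
#'
#' @param fm a \linkS4class{FeatureMatrix}
#' @param params \linkS4class{ScalingParams} from \code{\link{fitScaler}}
#' @return a scaled \linkS4class{FeatureMatrix} (dropped columns removed)
#' @export
applyScaler <- function(fm, params) {
  if (fm@scaled) stop("matrix is already scaled (division is not idempotent)")
  unseen <- setdiff(names(params@sds), colnames(fm@mat))
  if (length(unseen) > 0L)
    stop("columns missing from matrix: ", paste(unseen, collapse = ", "))
  mat <- fm@mat[, names(params@sds), drop = FALSE]
  mat <- sweep(mat, 2L, params@sds, "/")
  new("FeatureMatrix", mat = mat, scaled = TRUE, checksum = fm@checksum)
}
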