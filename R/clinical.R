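# Clinical-variable cleaning, ordinal/categorical encoding, and the
# 6-dimensional clinical encoder (a small dense network whose weights are
# trained jointly with the fusion model; this file defines the forward map
# and the fitted cleaning schema applied identically to new patients).

# Recognise ordered stage/grade level patterns and return levels in
# severity order, or NULL if the variable is not recognisably ordinal.
ordinal_levels <- function(values) {
  v <- unique(values[!is.na(values)])
  strip <- toupper(trimws(sub("(?i)^stage\\s*", "", v, perl = TRUE)))
  roman <- c("I", "II", "III", "IV", "V")
  # Roman-numeral stages, optionally with a/b sub-stage suffixes.
  base <- sub("[AB]$", "", strip)
  if (all(base %in% roman)) {
    ord <- order(match(base, roman), strip)
    return(v[ord])
  }
  # Letter-digit codes: T1..T4, N0..N3, M0/M1, G1..G4, ...
  if (all(grepl("^[A-Z][0-9]+[AB]?$", strip)) &&
      length(unique(substr(strip, 1, 1))) == 1L) {
    num <- as.numeric(sub("^[A-Z]([0-9]+)[AB]?$", "\\1", strip))
    return(v[order(num, strip)])
  }
  NULL
}

.mode_value <- function(x) {
  x <- x[!is.na(x)]
  names(sort(table(x), decreasing = TRUE))[1L]
}

#' Clean a clinical table and fit its encoding schema
#'
#' Drops variables whose missing fraction exceeds `missing_threshold` or
#' whose variance after numeric encoding is at or below
#' `variance_threshold`; encodes ordinal stage/grade variables by severity
#' order (I < II < III < IV, T1 < T2 < ..., N0 < N1 < ...) and other
#' categorical variables by level codes; imputes remaining missing values
#' (median for numeric/ordinal, mode for categorical). Every drop is
#' recorded with its reason. The returned schema reapplies the identical
#' transformation to new patients via [apply_clinical_schema()].
#'
#' @param table Data frame of raw clinical variables (no patient_id
#'   column); `NA` or empty strings mark missing values.
#' @param missing_threshold Maximum tolerated missing fraction (default 0.2).
#' @param variance_threshold Variables with encoded variance at or below
#'   this are dropped (default 1e-8).
#' @param preset Optional variable preset restricting which variables are
#'   considered: `"hnsc"` (age, clinical stage, tumor grade, pathological
#'   T/N stage) or `"brca"` (age, pathological grade, pathological M/N/T
#'   stage).
#' @return A list of class `clinical_clean`: `table` (imputed numeric
#'   matrix as data frame), `schema` (per-variable type, encoding map,
#'   imputation value), and `dropped` (data frame of variable, reason).
#' @export
clean_clinical <- function(table, missing_threshold = 0.2,
                           variance_threshold = 1e-8, preset = NULL) {
  table <- as.data.frame(table, stringsAsFactors = FALSE)
  if (!is.null(preset)) {
    keep <- clinical_preset(preset)
    keep <- intersect(keep, names(table))
    table <- table[, keep, drop = FALSE]
  }
  for (j in seq_along(table)) {
    if (is.character(table[[j]])) table[[j]][trimws(table[[j]]) == ""] <- NA
  }
  schema <- list()
  dropped <- data.frame(variable = character(), reason = character(),
                        stringsAsFactors = FALSE)
  out <- list()
  for (nm in names(table)) {
    col <- table[[nm]]
    miss <- mean(is.na(col))
    if (miss > missing_threshold) {
      dropped <- rbind(dropped, data.frame(
        variable = nm,
        reason = sprintf("missing fraction %.2f > %.2f", miss,
                         missing_threshold)))
      next
    }
    if (is.numeric(col)) {
      type <- "numeric"; enc <- col; map <- NULL
      impute <- stats::median(col, na.rm = TRUE)
      enc[is.na(enc)] <- impute
    } else {
      lev <- ordinal_levels(col)
      if (!is.null(lev)) {
        type <- "ordinal"
        map <- stats::setNames(seq_along(lev), lev)
        enc <- unname(map[col])
        impute_code <- stats::median(enc, na.rm = TRUE)
        enc[is.na(enc)] <- impute_code
        impute <- impute_code
      } else {
        type <- "categorical"
        lev <- sort(unique(col[!is.na(col)]))
        map <- stats::setNames(seq_along(lev), lev)
        impute_level <- .mode_value(col)
        col[is.na(col)] <- impute_level
        enc <- unname(map[col])
        impute <- unname(map[impute_level])
      }
    }
    if (stats::var(enc) <= variance_threshold) {
      dropped <- rbind(dropped, data.frame(
        variable = nm, reason = "variance at or below threshold"))
      next
    }
    schema[[nm]] <- list(type = type, map = map, impute = impute)
    out[[nm]] <- enc
  }
  if (length(out) == 0L) stop("all clinical variables were dropped")
  for (d in seq_len(nrow(dropped))) {
    message(sprintf("clean_clinical: dropped %s (%s)",
                    dropped$variable[d], dropped$reason[d]))
  }
  structure(list(table = as.data.frame(out, check.names = FALSE),
                 schema = schema, dropped = dropped,
                 missing_threshold = missing_threshold,
                 variance_threshold = variance_threshold),
            class = "clinical_clean")
}

#' Variable presets for the two supported disease sites
#' @param name `"hnsc"` or `"brca"`.
#' @return Character vector of variable names.
#' @export
clinical_preset <- function(name) {
  switch(tolower(name),
    hnsc = c("age", "clinical_stage", "tumor_grade", "path_t_stage",
             "path_n_stage"),
    brca = c("age", "path_grade", "path_m_stage", "path_n_stage",
             "path_t_stage"),
    stop("unknown preset: ", name)
  )
}

#' Apply a fitted cleaning schema to new patients
#'
#' Encodes and imputes a raw clinical table using the variable list,
#' encoding maps and imputation values fitted by [clean_clinical()] on the
#' training patients. Unseen categorical/ordinal levels map to a dedicated
#' code 0 with a warning.
#'
#' @param clean A `clinical_clean` schema.
#' @param table Raw clinical data frame for new patients.
#' @return Numeric data frame with the schema's variables, fully imputed.
#' @export
apply_clinical_schema <- function(clean, table) {
  table <- as.data.frame(table, stringsAsFactors = FALSE)
  out <- list()
  for (nm in names(clean$schema)) {
    sc <- clean$schema[[nm]]
    if (!nm %in% names(table)) stop("missing clinical variable: ", nm)
    col <- table[[nm]]
    if (is.character(col)) col[trimws(col) == ""] <- NA
    if (sc$type == "numeric") {
      enc <- as.numeric(col)
      enc[is.na(enc)] <- sc$impute
    } else {
      enc <- unname(sc$map[as.character(col)])
      unseen <- !is.na(col) & is.na(enc)
      if (any(unseen)) {
        warning(sprintf("unseen level(s) in %s mapped to 'unknown' code: %s",
                        nm, paste(unique(col[unseen]), collapse = ", ")))
        enc[unseen] <- 0
      }
      enc[is.na(enc)] <- sc$impute
    }
    out[[nm]] <- enc
  }
  as.data.frame(out, check.names = FALSE)
}

#' Clinical encoder architecture
#'
#' A dense network mapping the cleaned numeric clinical variables to the
#' 6-dimensional clinical representation consumed by the fusion model. Its
#' weights live inside the fusion model and are trained end-to-end with the
#' fusion loss; this spec defines the forward map.
#'
#' @param input_dim Number of cleaned clinical variables.
#' @param output_dim Width of the clinical representation (default 6).
#' @param hidden Hidden-layer width (default 16).
#' @param seed Initialisation seed used when encoding with fresh weights.
#' @return A list of class `clinical_encoder_spec`.
#' @export
clinical_encoder_spec <- function(input_dim, output_dim = 6, hidden = 16,
                                  seed = 1) {
  stopifnot(input_dim >= 1, output_dim >= 1, hidden >= 1)
  structure(as.list(environment()), class = "clinical_encoder_spec")
}

.clin_init <- function(spec) {
  list(Wc1 = glorot(spec$input_dim, spec$hidden),
       bc1 = numeric(spec$hidden),
       Wc2 = glorot(spec$hidden, spec$output_dim),
       bc2 = numeric(spec$output_dim))
}

.clin_forward <- function(x, params) {
  h <- relu(sweep(x %*% params$Wc1, 2, params$bc1, "+"))
  list(h = h, out = sweep(h %*% params$Wc2, 2, params$bc2, "+"))
}

#' Encode cleaned clinical variables to the 6-dimensional representation
#'
#' Standardizes each variable (using the supplied or freshly computed
#' centring) and applies the clinical encoder forward map. When no trained
#' parameters are given, deterministic seeded initial weights are used, so
#' the map is reproducible but untrained.
#'
#' @param table Numeric data frame from [clean_clinical()] /
#'   [apply_clinical_schema()].
#' @param spec A [clinical_encoder_spec()]; defaults to one sized for
#'   `table`.
#' @param params Optional trained encoder weights (from a fusion fit).
#' @param standardize Optional list with `center` and `scale` vectors; when
#'   `NULL` they are computed from `table`.
#' @return Matrix (patients x `output_dim`) with attribute `standardize`.
#' @export
encode_clinical <- function(table, spec = NULL, params = NULL,
                            standardize = NULL) {
  x <- as.matrix(table)
  if (!is.numeric(x)) stop("clinical table must be numeric after cleaning")
  if (is.null(spec)) spec <- clinical_encoder_spec(input_dim = ncol(x))
  if (ncol(x) != spec$input_dim) stop("input_dim must equal ncol(table)")
  if (is.null(standardize)) {
    ctr <- colMeans(x)
    scl <- apply(x, 2, stats::sd)
    scl[scl == 0] <- 1
    standardize <- list(center = ctr, scale = scl)
  }
  x <- sweep(sweep(x, 2, standardize$center), 2, standardize$scale, "/")
  if (is.null(params)) params <- with_seed(spec$seed, .clin_init(spec))
  out <- .clin_forward(x, params)$out
  attr(out, "standardize") <- standardize
  out
}
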