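#' Disability-weight registry for the 13 chronic diseases
#'
#' Builds the fixed table of disability weights used to convert disease
#' durations into years lived with disability (YLDs). Weights are severity
#' scores in \[0, 1\] (0 = full health, 1 = death), drawn from GBD-2013
#' health-state valuations supplemented by China-specific (hypertension) and
#' WHO (diabetes) studies. Four entries are composites formed as the
#' unweighted arithmetic mean of component health-state weights; the hepatic
#' composite averages decompensated liver cirrhosis (lower limit, 0.123) and
#' viral hepatitis (0.006). Hyperlipidemia, although present in the
#' 14-disease questionnaire battery, carries no weight and is excluded.
#'
#' @return A `daly_weight_table`: a data frame with columns `disease`
#'   (identifier), `weight` (numeric in \[0,1\]), `source` (provenance
#'   label), `composite` (logical), and `components` (list column of numeric
#'   component weights, named where the components are published; `NA` for
#'   composites whose source reports only the mean).
#' @examples
#' wt <- disease_weights()
#' wt[wt$disease == "hypertension", "weight"]
#' @export
disease_weights <- function() {
  entries <- list(
    list("hypertension",        0.36,   "Studies in China", FALSE, NULL),
    list("diabetes",            0.015,  "WHO studies", FALSE, NULL),
    list("cancer",              0.288,  "Cancer diagnosis and primary treatment", FALSE, NULL),
    list("chronic_lung_disease",0.225,  "Moderate chronic pulmonary disease", FALSE, NULL),
    list("hepatic_disease",     0.0645, "Mean of decompensated liver cirrhosis (lower limit) and viral hepatitis",
         TRUE, c(decompensated_cirrhosis_lower = 0.123, viral_hepatitis = 0.006)),
    list("heart_disease",       0.008,  "Moderate angina pectoris", FALSE, NULL),
    list("stroke",              0.07,   "Moderate stroke", FALSE, NULL),
    list("kidney_disease",      0.104,  "Chronic kidney disease (stage 4)", FALSE, NULL),
    list("gastric_disease",     0.209,  "Gastric bleeding lower limit value", FALSE, NULL),
    list("emotional_mental",    0.265,  "Mean of moderate anxiety and depression",
         TRUE, NA_real_),
    list("memory_disease",      0.322,  "Mean of moderate dementia and Parkinson's disease",
         TRUE, NA_real_),
    list("arthritis_rheumatism",0.080,  "Mean of moderate musculoskeletal disorders",
         TRUE, NA_real_),
    list("asthma",              0.036,  "Partly controlled asthma", FALSE, NULL)
  )
  tab <- data.frame(
    disease   = vapply(entries, `[[`, character(1), 1L),
    weight    = vapply(entries, `[[`, numeric(1), 2L),
    source    = vapply(entries, `[[`, character(1), 3L),
    composite = vapply(entries, `[[`, logical(1), 4L),
    stringsAsFactors = FALSE
  )
  tab$components <- lapply(entries, `[[`, 5L)
  class(tab) <- c("daly_weight_table", "data.frame")
  validate_weight_table(tab)
  tab
}

#' @export
print.daly_weight_table <- function(x, ...) {
  cat("Disability-weight table:", nrow(x), "chronic diseases\n")
  df <- data.frame(disease = x$disease, weight = x$weight,
                   composite = ifelse(x$composite, "*", ""))
  print(df, row.names = FALSE)
  invisible(x)
}

validate_weight_table <- function(tab) {
  stopifnot(inherits(tab, "data.frame"))
  if (nrow(tab) != 13L)
    stop("weight table must contain exactly 13 disease entries, got ", nrow(tab))
  if (anyDuplicated(tab$disease))
    stop("duplicate disease identifiers in weight table")
  if (any(tab$weight < 0 | tab$weight > 1))
    stop("disability weights must lie in [0, 1]")
  if ("hyperlipidemia" %in% tab$disease)
    stop("hyperlipidemia carries no disability weight and must not appear")
  # composite entries with published numeric components must equal their mean
  for (i in which(tab$composite)) {
    comp <- tab$components[[i]]
    if (is.numeric(comp) && !anyNA(comp) && length(comp) > 1) {
      if (abs(tab$weight[i] - mean(comp)) > 1e-8)
        stop("composite weight for ", tab$disease[i],
             " does not equal the mean of its components")
    }
  }
  invisible(tab)
}

#' Export or import a disability-weight table as CSV
#'
#' The CSV layout (`disease`, `weight`, `source`, `composite`, `components`
#' as `name=value` pairs separated by `;`) allows alternative weight sets to
#' be swapped in while keeping the same scoring pipeline.
#'
#' @param table a `daly_weight_table`.
#' @param path file path.
#' @return `write_weight_table()` returns `path` invisibly;
#'   `read_weight_table()` returns a validated `daly_weight_table`.
#' @export
write_weight_table <- function(table, path) {
  validate_weight_table(table)
  comp_str <- vapply(table$components, function(z) {
    if (is.null(z) || (length(z) == 1 && is.na(z))) return("")
    paste(sprintf("%s=%.10g", names(z), z), collapse = ";")
  }, character(1))
  out <- data.frame(disease = table$disease, weight = table$weight,
                    source = table$source, composite = table$composite,
                    components = comp_str, stringsAsFactors = FALSE)
  write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_weight_table
#' @export
read_weight_table <- function(path) {
  raw <- read.csv(path, stringsAsFactors = FALSE)
  raw$components <- lapply(raw$components, function(s) {
    if (is.na(s) || !nzchar(s)) return(NA_real_)
    kv <- strsplit(strsplit(s, ";", fixed = TRUE)[[1]], "=", fixed = TRUE)
    stats::setNames(vapply(kv, function(p) as.numeric(p[2]), numeric(1)),
                    vapply(kv, `[[`, character(1), 1L))
  })
  raw$components[!raw$composite] <- list(NULL)
  class(raw) <- c("daly_weight_table", "data.frame")
  validate_weight_table(raw)
  raw
}
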