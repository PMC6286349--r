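#' Food frequency questionnaire table
#'
#' Samples x food items matrix of daily consumption frequencies plus a
#' per-food annotation table (food group, health value in \[0, 1\], and
#' macronutrient composition per serving).
#'
#' @param values non-negative samples x foods numeric matrix.
#' @param foods data frame with one row per food column; must contain
#'   columns `food`, `food_group`, `health_value`, `protein_g`, `fat_g`,
#'   `carb_g`, `fibre_g`, `kcal`. Defaults to the packaged reference table.
#' @return object of class `ffq_table`.
#' @export
ffq_table <- function(values, foods = food_reference()) {
  if (any(!is.finite(values)) || any(values < 0))
    stop_invalid("FFQ values must be finite and non-negative")
  needed <- c("food", "food_group", "health_value", "protein_g", "fat_g",
              "carb_g", "fibre_g", "kcal")
  if (!all(needed %in% names(foods)))
    stop_invalid("food annotation table lacks columns: ",
                 paste(setdiff(needed, names(foods)), collapse = ", "))
  missing <- setdiff(colnames(values), foods$food)
  if (length(missing))
    stop_invalid("no annotation for foods: ", paste(missing, collapse = ", "))
  foods <- foods[match(colnames(values), foods$food), , drop = FALSE]
  if (any(foods$health_value < 0 | foods$health_value > 1))
    stop_invalid("health values must lie in [0, 1]")
  structure(list(values = values, foods = foods), class = "ffq_table")
}

#' @export
print.ffq_table <- function(x, ...) {
  cat(sprintf("ffq_table: %d samples x %d foods\n",
              nrow(x$values), ncol(x$values)))
  invisible(x)
}

ffq_values <- function(ffq) {
  if (inherits(ffq, "ffq_table")) ffq$values
  else if (is.matrix(ffq)) ffq
  else stop_invalid("expected an ffq_table or matrix")
}

#' Packaged food reference table
#'
#' Fifty food items with food group, a health value in \[0, 1\] used by the
#' Healthy Food Diversity index, and per-serving macronutrient composition
#' (grams of protein, fat, carbohydrate and fibre, and kilocalories). The
#' values are package defaults for simulation and worked examples; studies
#' with their own food composition data should pass a replacement table.
#'
#' @return data frame with 50 rows.
#' @export
food_reference <- function() {
  path <- system.file("extdata", "food_reference.csv", package = "microstrat",
                      mustWork = TRUE)
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Default FFQ frequency dialect
#'
#' Maps the questionnaire's categorical answers to daily consumption
#' frequencies. Point frequencies convert directly ("2 times per day" ->
#' 2); weekly ranges use the range midpoint divided by 7 ("1-3 times per
#' week" -> 2/7); the floor category "never or less than once a week" is 0
#' and the ceiling "4 or more times per day" is 4.
#'
#' @return named numeric vector: category string -> consumptions per day.
#' @export
ffq_dialect <- function() {
  per_week <- function(x) x / 7
  c("never or less than once a week" = 0,
    "1-3 times per week"             = per_week(2),
    "4-6 times per week"             = per_week(5),
    "1 time per day"                 = 1,
    "2 times per day"                = 2,
    "3 times per day"                = 3,
    "4 or more times per day"        = 4)
}

#' Convert categorical FFQ answers to daily consumption frequencies
#'
#' @param raw samples x foods character matrix (or data frame) of category
#'   strings.
#' @param dialect named numeric vector mapping category -> per-day value;
#'   defaults to [ffq_dialect()]. En and em dashes are normalized to "-"
#'   before lookup.
#' @param foods food annotation table for the resulting [ffq_table].
#' @return an [ffq_table] of daily consumption values.
#' @export
#' @examples
#' raw <- matrix(c("2 times per day", "1-3 times per week"), 1,
#'               dimnames = list("s1", c("milk_full_fat", "fish")))
#' convert_ffq_frequencies(raw)$values  # 2 and 2/7
convert_ffq_frequencies <- function(raw, dialect = ffq_dialect(),
                                    foods = food_reference()) {
  raw <- as.matrix(raw)
  cats <- gsub("–|—", "-", trimws(tolower(raw)))
  unknown <- setdiff(unique(as.vector(cats)), names(dialect))
  if (length(unknown))
    stop_invalid("unknown FFQ categories: ", paste(unknown, collapse = "; "))
  vals <- matrix(dialect[cats], nrow(raw), ncol(raw), dimnames = dimnames(raw))
  ffq_table(vals, foods = foods)
}

#' Healthy Food Diversity index
#'
#' A health-weighted Berry diversity index of the diet. With consumption
#' shares `s_i = c_i / sum(c)` and per-food health values `hv_i` in
#' \[0, 1\]: `HFD = (sum hv_i s_i) * (1 - sum s_i^2)`. The second factor is
#' the Berry index, zero for a single-food diet and maximal (1 - 1/n) for a
#' perfectly even one; the first factor discounts diversity achieved with
#' unhealthy foods.
#'
#' @param ffq an [ffq_table] (uses its health-value annotations) or a
#'   numeric matrix together with `health_values`.
#' @param health_values optional numeric vector overriding the annotation.
#' @return named numeric vector of per-sample HFD values in
#'   \[0, 1 - 1/n_foods\].
#' @export
#' @examples
#' m <- matrix(c(1, 1), 1, dimnames = list("s1", c("fish", "crisps")))
#' hfd_index(m, health_values = c(1, 0))  # 0.5 * 0.5 = 0.25
hfd_index <- function(ffq, health_values = NULL) {
  vals <- ffq_values(ffq)
  hv <- health_values %||%
    (if (inherits(ffq, "ffq_table")) ffq$foods$health_value else
       stop_invalid("health_values required when ffq is a plain matrix"))
  if (length(hv) != ncol(vals))
    stop_invalid("need one health value per food")
  tot <- rowSums(vals)
  if (any(tot <= 0))
    stop_invalid("samples with zero total consumption: ",
                 paste(rownames(vals)[tot <= 0], collapse = ", "))
  shares <- vals / tot
  drop(shares %*% hv) * (1 - rowSums(shares^2))
}

#' Per-sample macronutrient summary
#'
#' Converts daily consumptions and per-serving composition into the share
#' of daily kilocalories from protein, fat and carbohydrate (Atwater
#' factors 4/9/4 kcal per gram) and fibre intake as grams per 1000 kcal.
#' The macronutrient shares sum to at most 100%; the remainder (alcohol or
#' unassigned energy in the food composition data) is reported.
#'
#' @param ffq an [ffq_table].
#' @return data frame per sample: `protein_pct`, `fat_pct`, `carb_pct`,
#'   `other_pct`, `fibre_g_per_1000kcal`, `kcal`.
#' @export
macronutrient_summary <- function(ffq) {
  if (!inherits(ffq, "ffq_table")) stop_invalid("expected an ffq_table")
  vals <- ffq$values
  f <- ffq$foods
  grams <- function(col) drop(vals %*% f[[col]])
  kcal <- drop(vals %*% f$kcal)
  if (any(kcal <= 0))
    stop_invalid("samples with zero energy intake: ",
                 paste(rownames(vals)[kcal <= 0], collapse = ", "))
  protein_kcal <- 4 * grams("protein_g")
  fat_kcal <- 9 * grams("fat_g")
  carb_kcal <- 4 * grams("carb_g")
  out <- data.frame(
    protein_pct = 100 * protein_kcal / kcal,
    fat_pct = 100 * fat_kcal / kcal,
    carb_pct = 100 * carb_kcal / kcal,
    fibre_g_per_1000kcal = 1000 * grams("fibre_g") / kcal,
    kcal = kcal,
    row.names = rownames(vals)
  )
  out$other_pct <- pmax(0, 100 - out$protein_pct - out$fat_pct - out$carb_pct)
  out[, c("protein_pct", "fat_pct", "carb_pct", "other_pct",
          "fibre_g_per_1000kcal", "kcal")]
}
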