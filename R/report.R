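#' Cohort characteristics stratified by sepsis status
#'
#' Builds the classic "Table 1"-style characteristics table: for each
#' variable, per-category counts and row percentages by sepsis status and a
#' chi-square test of independence. Age is banded 18-44 / 45-64 / 65+;
#' comorbidity flags are tested as 2x2 tables of flag presence versus
#' sepsis. Row percentages follow the convention of reporting what fraction
#' of each category's row is sepsis versus non-sepsis.
#'
#' Pearson's chi-square is computed without continuity correction for
#' tables larger than 2x2; for 2x2 tables the Yates correction is off by
#' default and exposed via `correct2x2`. For multi-category variables a
#' likelihood-ratio (G) test is available as an alternative via
#' `multiLevelTest = "lrt"`. A variable with an all-zero category (expected
#' count 0) has its test skipped with a warning and `NA` p-value.
#'
#' @param encounterTable data.frame of encounters, e.g.
#'   `encounters(cohort)`.
#' @param labels data.frame from [labelCohort()] (or any data.frame with
#'   `encounter_id` and logical `sepsis`).
#' @param variables character vector of variables to tabulate; any of
#'   `"sex"`, `"age_band"`, `"race"` and the comorbidity flags. Defaults to
#'   all of them.
#' @param correct2x2 apply the Yates continuity correction to 2x2 tables.
#' @param multiLevelTest `"chisq"` (Pearson, default) or `"lrt"`
#'   (likelihood-ratio G test) for variables with more than two categories.
#' @return data.frame of class `characteristicsTable`: `variable`,
#'   `category`, `n_nosepsis`, `pct_nosepsis`, `n_sepsis`, `pct_sepsis`,
#'   and (on each variable's first row) `statistic`, `df`, `p_value`.
#' @export
characteristicsTable <- function(encounterTable, labels, variables = NULL,
                                 correct2x2 = FALSE,
                                 multiLevelTest = c("chisq", "lrt")) {
  multiLevelTest <- match.arg(multiLevelTest)
  enc <- as.data.frame(encounterTable)
  lab <- as.data.frame(labels)
  i <- match(enc$encounter_id, lab$encounter_id)
  if (anyNA(i))
    stop("every encounter must have a sepsis label", call. = FALSE)
  sepsis <- lab$sepsis[i]
  enc$age_band <- cut(enc$age_years, breaks = c(18, 45, 65, Inf),
                      labels = c("18-44", "45-64", "65+"), right = FALSE)
  if (is.null(variables))
    variables <- c("sex", "age_band", "race", .COMORBIDITIES)

  one <- function(v) {
    if (v %in% .COMORBIDITIES) {
      # 2x2 test on flag x sepsis; report the flag-present row only
      f <- factor(enc[[v]] %in% TRUE, levels = c(FALSE, TRUE))
      tab <- table(f, factor(sepsis, levels = c(FALSE, TRUE)))
      rows <- data.frame(variable = v, category = v,
                         n_nosepsis = tab["TRUE", "FALSE"],
                         n_sepsis = tab["TRUE", "TRUE"])
    } else {
      f <- factor(enc[[v]])
      tab <- table(f, factor(sepsis, levels = c(FALSE, TRUE)))
      rows <- data.frame(variable = v, category = rownames(tab),
                         n_nosepsis = as.integer(tab[, "FALSE"]),
                         n_sepsis = as.integer(tab[, "TRUE"]))
    }
    tot <- rows$n_nosepsis + rows$n_sepsis
    rows$pct_nosepsis <- ifelse(tot > 0, 100 * rows$n_nosepsis / tot, NA)
    rows$pct_sepsis <- ifelse(tot > 0, 100 * rows$n_sepsis / tot, NA)
    rows$statistic <- rows$df <- rows$p_value <- NA_real_
    test <- .chisqIndependence(tab, correct2x2, multiLevelTest, v)
    rows$statistic[1] <- test$statistic
    rows$df[1] <- test$df
    rows$p_value[1] <- test$p
    rows
  }
  out <- do.call(rbind, lapply(variables, one))
  rownames(out) <- NULL
  out <- out[, c("variable", "category", "n_nosepsis", "pct_nosepsis",
                 "n_sepsis", "pct_sepsis", "statistic", "df", "p_value")]
  class(out) <- c("characteristicsTable", "data.frame")
  out
}

.chisqIndependence <- function(tab, correct2x2, multiLevelTest, varName) {
  tab <- tab[rowSums(tab) > 0, , drop = FALSE]
  if (nrow(tab) < 2 || any(colSums(tab) == 0) ||
      any(outer(rowSums(tab), colSums(tab)) / sum(tab) == 0)) {
    warning("test skipped for '", varName,
            "': zero expected cell count", call. = FALSE)
    return(list(statistic = NA_real_, df = NA_real_, p = NA_real_))
  }
  if (nrow(tab) > 2 && multiLevelTest == "lrt") {
    exp <- outer(rowSums(tab), colSums(tab)) / sum(tab)
    obs <- as.numeric(tab)
    g <- 2 * sum(ifelse(obs > 0, obs * log(obs / as.numeric(exp)), 0))
    df <- (nrow(tab) - 1) * (ncol(tab) - 1)
    return(list(statistic = g, df = df, p = pchisq(g, df, lower.tail = FALSE)))
  }
  ct <- suppressWarnings(
    chisq.test(tab, correct = if (nrow(tab) == 2) correct2x2 else FALSE))
  list(statistic = unname(ct$statistic), df = unname(ct$parameter),
       p = ct$p.value)
}

#' @export
print.characteristicsTable <- function(x, ...) {
  cat("Cohort characteristics by sepsis status (chi-square tests)\n")
  df <- as.data.frame(x)
  df$pct_nosepsis <- sprintf("%.1f", df$pct_nosepsis)
  df$pct_sepsis <- sprintf("%.1f", df$pct_sepsis)
  df$p_value <- ifelse(is.na(df$p_value), "",
                       ifelse(df$p_value < 0.01, "<.01",
                              sprintf("%.2g", df$p_value)))
  df$statistic <- ifelse(is.na(df$statistic), "",
                         sprintf("%.1f", df$statistic))
  df$df <- ifelse(is.na(df$df), "", as.character(df$df))
  print(df, row.names = FALSE)
  invisible(x)
}
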