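# Individual-level life-history observations from constant-temperature
# experiments: the fitting input.  Three record types are kept in separate
# data frames but travel together in one object (and one CSV):
#   immatures: one row per individual exposed as an egg
#              (temperature, id, survived, dev_days).
#   adults:    one row per adult followed for longevity
#              (temperature, id, sex, death_day).
#   eggs:      one row per female-day with a count of eggs laid
#              (temperature, id, adult_age, eggs); ids refer to female
#              rows in `adults`.

#' Life-history observation set
#'
#' @param immatures data frame with columns `temperature`, `id`,
#'   `survived` (logical) and `dev_days` (days, `NA` for individuals that
#'   died before emergence).
#' @param adults data frame with columns `temperature`, `id`, `sex`
#'   (`"F"`/`"M"`) and `death_day` (days of adult life).
#' @param eggs data frame with columns `temperature`, `id`, `adult_age`
#'   and `eggs` (daily egg counts for females in `adults`).
#' @return an object of class `life_history`.
#' @export
life_history <- function(immatures = NULL, adults = NULL, eggs = NULL) {
  empty <- function(cols) {
    as.data.frame(stats::setNames(rep(list(numeric(0)), length(cols)), cols))
  }
  immatures <- immatures %||%
    empty(c("temperature", "id", "survived", "dev_days"))
  adults <- adults %||% empty(c("temperature", "id", "sex", "death_day"))
  eggs <- eggs %||% empty(c("temperature", "id", "adult_age", "eggs"))

  need <- function(df, cols, what) {
    miss <- setdiff(cols, names(df))
    if (length(miss)) {
      stop_invalid(what, " records missing column(s): ",
                   paste(miss, collapse = ", "))
    }
  }
  need(immatures, c("temperature", "id", "survived", "dev_days"), "immature")
  need(adults, c("temperature", "id", "sex", "death_day"), "adult")
  need(eggs, c("temperature", "id", "adult_age", "eggs"), "egg")
  ok <- is.na(immatures$dev_days) | immatures$dev_days > 0
  if (!all(ok)) stop_invalid("development times must be > 0")
  if (nrow(eggs) && any(eggs$eggs < 0)) {
    stop_invalid("egg counts must be >= 0")
  }
  structure(list(immatures = immatures, adults = adults, eggs = eggs),
            class = "life_history")
}

#' @export
print.life_history <- function(x, ...) {
  cat("<life_history>\n")
  cat(sprintf("  immatures: %d individuals over %d temperatures\n",
              nrow(x$immatures), length(unique(x$immatures$temperature))))
  cat(sprintf("  adults:    %d individuals over %d temperatures\n",
              nrow(x$adults), length(unique(x$adults$temperature))))
  cat(sprintf("  egg records: %d female-days\n", nrow(x$eggs)))
  invisible(x)
}

#' Write life-history observations to CSV
#'
#' One file with a `record` discriminator column (`immature`, `adult`,
#' `egg`); fields not applicable to a record type are left empty.
#'
#' @param obs a [life_history()] object.
#' @param path file path.
#' @return `path`, invisibly.
#' @export
write_life_history <- function(obs, path) {
  stopifnot(inherits(obs, "life_history"))
  blank <- function(n) rep(NA, n)
  im <- data.frame(record = rep("immature", nrow(obs$immatures)),
                   temperature = obs$immatures$temperature,
                   id = obs$immatures$id,
                   sex = blank(nrow(obs$immatures)),
                   survived = obs$immatures$survived,
                   dev_days = obs$immatures$dev_days,
                   death_day = blank(nrow(obs$immatures)),
                   adult_age = blank(nrow(obs$immatures)),
                   eggs = blank(nrow(obs$immatures)))
  ad <- data.frame(record = rep("adult", nrow(obs$adults)),
                   temperature = obs$adults$temperature,
                   id = obs$adults$id,
                   sex = obs$adults$sex,
                   survived = blank(nrow(obs$adults)),
                   dev_days = blank(nrow(obs$adults)),
                   death_day = obs$adults$death_day,
                   adult_age = blank(nrow(obs$adults)),
                   eggs = blank(nrow(obs$adults)))
  eg <- data.frame(record = rep("egg", nrow(obs$eggs)),
                   temperature = obs$eggs$temperature,
                   id = obs$eggs$id,
                   sex = blank(nrow(obs$eggs)),
                   survived = blank(nrow(obs$eggs)),
                   dev_days = blank(nrow(obs$eggs)),
                   death_day = blank(nrow(obs$eggs)),
                   adult_age = obs$eggs$adult_age,
                   eggs = obs$eggs$eggs)
  utils::write.csv(rbind(im, ad, eg), path, row.names = FALSE, na = "")
  invisible(path)
}

#' Read life-history observations from CSV
#'
#' @param path file written by [write_life_history()] (or following the
#'   same schema).
#' @return a [life_history()] object.
#' @export
read_life_history <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (nrow(df) == 0) stop_invalid("empty observations file: ", path)
  required <- c("record", "temperature", "id")
  miss <- setdiff(required, names(df))
  if (length(miss)) {
    stop_invalid("observations file missing column(s): ",
                 paste(miss, collapse = ", "))
  }
  bad <- !df$record %in% c("immature", "adult", "egg")
  if (any(bad)) {
    stop_invalid("unknown record type in row ", which(bad)[1], ": '",
                 df$record[which(bad)[1]], "'")
  }
  pick <- function(type, cols) {
    sub <- df[df$record == type, c("temperature", "id", cols), drop = FALSE]
    rownames(sub) <- NULL
    sub
  }
  im <- pick("immature", c("survived", "dev_days"))
  if (nrow(im)) im$survived <- as.logical(im$survived)
  life_history(immatures = im,
               adults = pick("adult", c("sex", "death_day")),
               eggs = pick("egg", c("adult_age", "eggs")))
}
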