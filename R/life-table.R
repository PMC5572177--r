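# Life-table handling and a synthetic female life table.

#' Synthetic female life table (Gompertz)
#'
#' Annual death probabilities `qx` for ages `start_age` to `max_age` from a
#' Gompertz hazard \eqn{\mu(x) = A e^{B (x - 60)}}. The default constants
#' are calibrated so the complete life expectancy at age 60 is 25.22 years,
#' matching published UK female period life-table values; this is a
#' synthetic stand-in for a national life table, adequate for cohort
#' modelling but not an official statistic.
#'
#' @param start_age,max_age modelled age range; `qx` at `max_age` is forced
#'   to 1 so the cohort is fully absorbed within the table.
#' @param gompertz_a,gompertz_b Gompertz level (at age 60) and slope.
#' @return Data frame of class `life_table` with columns `age`, `qx`.
#' @examples
#' lt <- gompertz_life_table()
#' sum(cumprod(1 - lt$qx))  # curtate life expectancy at 60, ~24.7 y
#' @export
gompertz_life_table <- function(start_age = 60, max_age = 110,
                                gompertz_a = 4.93693e-3,
                                gompertz_b = 0.105) {
  stopifnot(max_age > start_age, gompertz_a > 0, gompertz_b > 0)
  ages <- seq(start_age, max_age)
  cumh <- function(t) gompertz_a / gompertz_b * (exp(gompertz_b * t) - 1)
  qx <- 1 - exp(-(cumh(ages - 59) - cumh(ages - 60)))
  qx[length(qx)] <- 1
  structure(data.frame(age = ages, qx = qx),
            class = c("life_table", "data.frame"))
}

#' Read or write a life table CSV (`age,qx`)
#'
#' @param path CSV file with columns `age` (years) and `qx` (annual death
#'   probability).
#' @return `read_life_table` returns a validated `life_table` data frame.
#' @export
read_life_table <- function(path) {
  lt <- as.data.frame(data.table::fread(path))
  if (!all(c("age", "qx") %in% names(lt)))
    stop("life table CSV must have columns 'age' and 'qx'", call. = FALSE)
  lt <- lt[order(lt$age), c("age", "qx")]
  if (any(lt$qx < 0 | lt$qx > 1))
    stop("'qx' values must lie in [0, 1]", call. = FALSE)
  if (any(diff(lt$age) != 1))
    stop("life-table ages must be contiguous", call. = FALSE)
  structure(lt, class = c("life_table", "data.frame"))
}

#' @rdname read_life_table
#' @param life_table a `life_table` data frame.
#' @export
write_life_table <- function(life_table, path) {
  data.table::fwrite(as.data.frame(life_table), path)
  invisible(path)
}

life_table_qx <- function(life_table, age) {
  i <- match(age, life_table$age)
  if (is.na(i)) {
    if (age > max(life_table$age)) return(1)
    stop(sprintf("age %d not covered by the life table", age),
         call. = FALSE)
  }
  life_table$qx[i]
}
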