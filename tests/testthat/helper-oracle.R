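# Independent brute-force classifier: direct inequality checks written
# separately from the production band logic, used as an oracle.

oracle_classify <- function(x, y, t_low, t_high, mode = "full") {
  stopifnot(length(x) == 1, length(y) == 1)
  if (mode == "fourway") {
    if (abs(x) < t_low && abs(y) < t_low) {
      return(list(quadrant = NA_character_, region = NA_character_,
                  reported = FALSE))
    }
    q <- if (x >= 0 && y >= 0) "Q1" else if (x < 0 && y >= 0) "Q2" else
      if (x < 0 && y < 0) "Q3" else "Q4"
    return(list(quadrant = q, region = NA_character_, reported = TRUE))
  }
  ax <- abs(x)
  ay <- abs(y)
  region <-
    if (ax >= t_high && ay >= t_high) "A" else
    if (ax >= t_high && ay >= t_low && ay < t_high) "C" else
    if (ax >= t_low && ax < t_high && ay >= t_high) "B" else
    if (ax >= t_high && ay < t_low) "D" else
    if (ax < t_low && ay >= t_high) "E" else
    if (ax >= t_low && ax < t_high && ay >= t_low && ay < t_high) "M" else
    if (ax >= t_low && ax < t_high && ay < t_low) "S" else
    if (ax < t_low && ay >= t_low && ay < t_high) "R" else
    NA_character_
  if (mode == "standard" && !is.na(region) &&
      region %in% c("M", "S", "R")) {
    region <- NA_character_
  }
  if (is.na(region)) {
    return(list(quadrant = NA_character_, region = NA_character_,
                reported = FALSE))
  }
  q <- if (x >= 0 && y >= 0) "Q1" else if (x < 0 && y >= 0) "Q2" else
    if (x < 0 && y < 0) "Q3" else "Q4"
  list(quadrant = q, region = region, reported = TRUE)
}
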