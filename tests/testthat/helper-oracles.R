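# Independent oracle for the classification axioms: every class is an
# intersection of a feature nominal and an enumerated property set, so the
# expected class set can be recomputed here from first principles.
oracle_classes <- function(feature, property) {
  mp <- c("steps", "distance", "elevation", "floors", "fair_activity",
          "high_activity", "light_activity", "sedentary")
  sp <- c("asleep_count", "asleep_duration", "awake_count", "awake_duration",
          "minutes_to_fall_asleep", "efficiency")
  hp <- c("heart_rate", "cardio", "fat_burn", "peak")
  out <- "Observation"
  if (feature == "movement" && property %in% mp) {
    out <- c(out, "MovementObservation")
    if (property %in% c("distance", "elevation", "floors", "steps"))
      out <- c(out, "WalkingFeature")
    if (property %in% c("fair_activity", "high_activity", "light_activity",
                        "sedentary"))
      out <- c(out, "MovementIntensity")
  }
  if (feature == "sleep" && property %in% sp) {
    out <- c(out, "SleepObservation")
    leaf <- c(asleep_count = "AsleepCount", asleep_duration = "AsleepDuration",
              awake_count = "AwakeCount", awake_duration = "AwakeDuration")
    if (property %in% names(leaf)) out <- c(out, unname(leaf[property]))
  }
  if (feature == "heart" && property %in% hp) {
    out <- c(out, "HeartObservation",
             c(heart_rate = "HeartRate", cardio = "Cardio",
               fat_burn = "FatBurn", peak = "Peak")[[property]])
  }
  sort(out)
}


# Brute-force window oracle: scan every minute between the first and last
# heart-rate sample, label minutes that carry a sample satisfying the HR
# comparison, read maximal runs off the labelling, and qualify each run by
# direct summation. Independent of the engine's run search.
oracle_windows <- function(steps, hr, rule) {
  h <- hr$samples
  out <- data.frame(start = as.POSIXct(character(), tz = "UTC"),
                    end = as.POSIXct(character(), tz = "UTC"),
                    length = integer(), total_steps = numeric())
  if (!nrow(h)) return(out)
  idx <- as.integer(floor(as.numeric(h$timestamp) / 60))
  lo <- min(idx); hi <- max(idx)
  cmp <- function(x, op, th) if (op == "<") x < th else x > th
  lab <- rep(FALSE, hi - lo + 1L)
  lab[idx - lo + 1L] <- cmp(h$value, rule$hr_comparator, rule$hr_threshold)
  r <- rle(lab)
  pos <- cumsum(c(1L, r$lengths))
  sidx <- as.integer(floor(as.numeric(steps$samples$timestamp) / 60))
  for (k in seq_along(r$values)) {
    if (!r$values[k]) next
    a <- lo + pos[k] - 1L
    b <- a + r$lengths[k]          # exclusive
    tot <- sum(steps$samples$value[sidx >= a & sidx < b])
    if (r$lengths[k] > rule$window_min_duration &&
        cmp(tot, rule$steps_comparator, rule$steps_threshold)) {
      out <- rbind(out, data.frame(
        start = as.POSIXct(a * 60, origin = "1970-01-01", tz = "UTC"),
        end = as.POSIXct(b * 60, origin = "1970-01-01", tz = "UTC"),
        length = r$lengths[k], total_steps = tot))
    }
  }
  rownames(out) <- NULL
  out
}

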