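# in-code fixtures: small schemas, random assessments, and an independent
# brute-force scoring oracle written directly from the schema definition

bin_factor <- function(id, weight) {
  list(id = id, text = id, weight = weight, response = list(kind = "binary"))
}

cat_factor <- function(id, weight, credits = c(0, 0.5, 1)) {
  list(id = id, text = id, weight = weight,
       response = list(kind = "categorical",
                       options = lapply(seq_along(credits), function(i) {
                         list(label = paste0(id, "_opt", i), credit = credits[i])
                       })))
}

thr_factor <- function(id, weight, threshold = 1, direction = ">=") {
  list(id = id, text = id, weight = weight,
       response = list(kind = "numeric_threshold", threshold = threshold,
                       direction = direction, units = "u"))
}

make_index <- function(id, slug, level, factors) {
  list(id = id, name = slug, slug = slug, level = level, factors = factors)
}

mini_schema <- function() {
  pigqsc:::new_schema("test", list(
    make_index(1, "mgmt", "farm",
               list(bin_factor("m_bin", 2), cat_factor("m_cat", 3),
                    thr_factor("m_thr", 5))),
    make_index(2, "rooms", "room",
               list(bin_factor("r_a", 10 / 3), bin_factor("r_b", 2.5),
                    bin_factor("r_c", 25 / 6)))
  ))
}

# random small schema: mixed factor kinds, random positive weights summing
# to 10 per index, a mix of farm- and room-level indices
random_schema <- function(n_idx = 3) {
  counter <- 0
  idxs <- lapply(seq_len(n_idx), function(i) {
    nf <- sample(3:8, 1)
    w <- runif(nf, 0.5, 2)
    w <- w / sum(w) * 10
    factors <- lapply(seq_len(nf), function(j) {
      counter <<- counter + 1
      id <- sprintf("f%d_%d", i, j)
      kind <- sample(c("bin", "cat", "thr"), 1)
      switch(kind,
             bin = bin_factor(id, w[j]),
             cat = cat_factor(id, w[j], credits = sort(c(0, runif(sample(0:2, 1)), 1))),
             thr = thr_factor(id, w[j], threshold = runif(1, 0.5, 2),
                              direction = sample(c(">=", "<="), 1)))
    })
    make_index(i, paste0("idx", i), sample(c("farm", "room"), 1), factors)
  })
  pigqsc:::new_schema("test", idxs)
}

random_value <- function(f) {
  r <- f$response
  if (r$kind == "binary") {
    sample(c("yes", "no"), 1)
  } else if (r$kind == "categorical") {
    sample(vapply(r$options, function(o) o$label, character(1)), 1)
  } else {
    format(max(0, r$threshold * runif(1, 0, 2)), digits = 10)
  }
}

random_assessment <- function(schema, farm_id = "farm", n_rooms = 2) {
  rows <- list()
  for (idx in schema$indices) {
    for (f in idx$factors) {
      if (idx$level == "farm") {
        rows[[length(rows) + 1]] <- data.frame(
          farm_id = farm_id, room_id = NA_character_, factor_id = f$id,
          value = random_value(f))
      } else {
        for (r in seq_len(n_rooms)) {
          rows[[length(rows) + 1]] <- data.frame(
            farm_id = farm_id, room_id = sprintf("room_%d", r),
            factor_id = f$id, value = random_value(f))
        }
      }
    }
  }
  do.call(rbind, rows)
}

# independent credit computation (deliberately separate from the package path)
oracle_credit <- function(f, value) {
  r <- f$response
  if (r$kind == "binary") {
    if (tolower(value) %in% c("yes", "true", "1", "y")) 1 else 0
  } else if (r$kind == "categorical") {
    for (o in r$options) if (o$label == value) return(o$credit)
    stop("bad label")
  } else {
    x <- as.numeric(value)
    if (r$direction == "<=") as.numeric(x <= r$threshold) else as.numeric(x >= r$threshold)
  }
}

oracle_overall <- function(responses, schema, farm) {
  sub <- responses[responses$farm_id == farm, ]
  total <- 0
  for (idx in schema$indices) {
    if (idx$level == "farm") {
      s <- 0
      for (f in idx$factors) {
        v <- sub$value[is.na(sub$room_id) & sub$factor_id == f$id]
        s <- s + f$weight * oracle_credit(f, v)
      }
    } else {
      rooms <- unique(sub$room_id[!is.na(sub$room_id)])
      per_room <- vapply(rooms, function(rm) {
        s <- 0
        for (f in idx$factors) {
          v <- sub$value[!is.na(sub$room_id) & sub$room_id == rm &
                           sub$factor_id == f$id]
          s <- s + f$weight * oracle_credit(f, v)
        }
        s
      }, numeric(1))
      s <- mean(per_room)
    }
    total <- total + s
  }
  total
}

# hand-computed percentile formulas for the two supported definitions
oracle_percentile <- function(x, q, method) {
  x <- sort(x)
  n <- length(x)
  pos <- if (method == "haverage") (n + 1) * q else 1 + (n - 1) * q
  pos <- min(max(pos, 1), n)
  lo <- floor(pos)
  frac <- pos - lo
  if (lo >= n) x[n] else x[lo] + frac * (x[lo + 1] - x[lo])
}
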