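# Independent brute-force reference implementation.  Everything here is
# plain per-person loops with exhaustive subset enumeration -- deliberately
# naive and structurally unrelated to the vectorised package code.

oracle_prefix_hit <- function(code, prefixes) {
  any(vapply(prefixes, function(p) startsWith(code, p), TRUE))
}

# Earliest identification date for ONE person's claims over [ws, we), or NA.
oracle_id_date <- function(pclaims, definition, ws, we) {
  candidates <- as.Date(character())
  for (cl in definition$clauses) {
    sel <- rep(FALSE, nrow(pclaims))
    for (i in seq_len(nrow(pclaims))) {
      sel[i] <- pclaims$source[i] == cl$source &&
        oracle_prefix_hit(pclaims$code[i], cl$code_prefixes) &&
        pclaims$service_date[i] >= ws && pclaims$service_date[i] < we
    }
    d <- sort(pclaims$service_date[sel])
    m <- cl$min_count
    if (length(d) >= m) {
      if (m == 1) {
        candidates <- c(candidates, min(d))
      } else {
        combs <- utils::combn(seq_along(d), m)
        for (j in seq_len(ncol(combs))) {
          sub <- d[combs[, j]]
          if (as.numeric(max(sub) - min(sub)) <= cl$within_days) {
            candidates <- c(candidates, max(sub))
          }
        }
      }
    }
  }
  if (length(candidates)) min(candidates) else as.Date(NA)
}

oracle_ascertain <- function(claims, definition, ws, we, ids) {
  out <- lapply(ids, function(id) {
    pc <- claims[claims$person_id == id, , drop = FALSE]
    d <- oracle_id_date(pc, definition, as.Date(ws), as.Date(we))
    tibble::tibble(person_id = id, identified = !is.na(d),
                   identification_date = d)
  })
  dplyr::bind_rows(out)
}

oracle_classify <- function(claims, definition, year, k, ids) {
  y_start <- as.Date(sprintf("%d-01-01", year))
  y_next <- as.Date(sprintf("%d-01-01", year + 1))
  lw_start <- as.Date(sprintf("%d-01-01", year - k))
  out <- lapply(ids, function(id) {
    pc <- claims[claims$person_id == id, , drop = FALSE]
    idd <- oracle_id_date(pc, definition, lw_start, y_next)
    prior <- if (k > 0) {
      !is.na(oracle_id_date(pc, definition, lw_start, y_start))
    } else FALSE
    tibble::tibble(
      person_id = id, disease = definition$disease_name,
      estimation_year = as.integer(year), k = as.integer(k),
      is_prevalent = !is.na(idd),
      is_at_risk = !prior,
      is_incident = !prior && !is.na(idd) && idd >= y_start,
      identification_date = idd)
  })
  dplyr::bind_rows(out)
}

oracle_counts <- function(cls) {
  list(n = nrow(cls),
       prevalent = sum(cls$is_prevalent),
       at_risk = sum(cls$is_at_risk),
       incident = sum(cls$is_incident))
}

oracle_misclassified_prevalent <- function(cls_k, cls_ref) {
  prev_ref <- cls_ref$person_id[cls_ref$is_prevalent]
  if (!length(prev_ref)) return(NA_real_)
  missed <- 0
  for (id in prev_ref) {
    if (!id %in% cls_k$person_id[cls_k$is_prevalent]) missed <- missed + 1
  }
  missed / length(prev_ref)
}

oracle_misclassified_incident <- function(cls_k, cls_ref) {
  inc_k <- cls_k$person_id[cls_k$is_incident]
  if (!length(inc_k)) return(NA_real_)
  hits <- 0
  for (id in inc_k) {
    if (id %in% cls_ref$person_id[!cls_ref$is_at_risk]) hits <- hits + 1
  }
  hits / length(inc_k)
}
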