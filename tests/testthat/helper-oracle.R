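# Independent one-dimensional oracle for the network solver.
#
# Re-derives the whole loss arithmetic from first principles (no calls into
# the package's hydraulics or solver code) and solves each tree-plus-shunt
# case by scalar bisection on the shunt flow, with a nested scalar solve
# for the bifurcation split (shunt at MPV) or the leak past the tee (shunt
# on a branch). Used to cross-check the package's general solver.

oracle_solve <- function(patient, position,
                         lengths = list(mpv = 0.040, lpv = 0.030,
                                        rpv = 0.030, tee = 0.010),
                         shunt_d = 0.008, shunt_l = 0.060,
                         k_entry = 0.45 + 0.25, re_threshold = 2300) {
  rho <- 1060
  mu <- 0.0035
  area <- function(d) pi * d^2 / 4
  fric <- function(q, d, l) {
    if (q == 0) return(0)
    v <- abs(q) / area(d)
    re <- rho * v * d / mu
    m <- if (re <= re_threshold) {
      128 * mu * l * abs(q) / (pi * d^4)
    } else {
      0.316 * re^-0.25 * (l / d) * rho * v^2 / 2
    }
    sign(q) * m
  }
  minor <- function(q, d, k) sign(q) * k * rho * (q / area(d))^2 / 2
  accel <- function(q, d_up, d_dn) {
    sign(q) * rho / 2 * ((q / area(d_dn))^2 - (q / area(d_up))^2)
  }
  bisect <- function(f, lo, hi, n = 200) {
    if (f(lo) > 0) return(lo)
    if (f(hi) < 0) return(hi)
    for (i in seq_len(n)) {
      mid <- (lo + hi) / 2
      if (mid == lo || mid == hi) break
      if (f(mid) < 0) lo <- mid else hi <- mid
    }
    (lo + hi) / 2
  }

  mm <- function(x) x / 1000
  d_mpv <- mm(patient$d_mpv)
  d_lpv <- mm(patient$d_lpv)
  d_rpv <- mm(patient$d_rpv)
  q_pre <- if (!is.null(patient$q_mpv_post)) patient$q_mpv_post / 2 else
    patient$v_mpv_pre * area(d_mpv)
  q_tot <- 2 * q_pre
  p_pa <- patient$p_pv * 133.322
  fr_l <- d_lpv^3 / (d_lpv^3 + d_rpv^3)
  r_l <- p_pa / (q_pre * fr_l)
  r_r <- p_pa / (q_pre * (1 - fr_l))

  shunt_loss <- function(qs, host_d) {
    accel(qs, host_d, shunt_d) + minor(qs, shunt_d, k_entry) +
      fric(qs, shunt_d, shunt_l)
  }

  if (position == "MPV") {
    # full branch segments downstream of the bifurcation
    branch_p <- function(q, d, l, r) fric(q, d, l) + accel(q, d_mpv, d) + r * q
    split_l <- function(q_h) {
      bisect(function(ql) {
        branch_p(ql, d_lpv, lengths$lpv, r_l) -
          branch_p(q_h - ql, d_rpv, lengths$rpv, r_r)
      }, 0, q_h)
    }
    resid <- function(qs) {
      q_h <- q_tot - qs
      ql <- split_l(q_h)
      p_bif <- branch_p(q_h - ql, d_rpv, lengths$rpv, r_r)
      shunt_loss(qs, d_mpv) - (p_bif + fric(q_h, d_mpv, lengths$tee))
    }
    qs <- bisect(resid, 0, q_tot)
    p_tee <- shunt_loss(qs, d_mpv)
    p_mid <- p_tee + fric(q_tot, d_mpv, lengths$mpv / 2 - lengths$tee)
  } else {
    host_d <- if (position == "LPV") d_lpv else d_rpv
    host_l <- if (position == "LPV") lengths$lpv else lengths$rpv
    r_host <- if (position == "LPV") r_l else r_r
    other_d <- if (position == "LPV") d_rpv else d_lpv
    other_l <- if (position == "LPV") lengths$rpv else lengths$lpv
    r_other <- if (position == "LPV") r_r else r_l
    leak_of <- function(p_tee) {
      bisect(function(qk) {
        fric(qk, host_d, host_l - lengths$tee) + r_host * qk - p_tee
      }, 0, q_tot)
    }
    resid <- function(qs) {
      p_tee <- shunt_loss(qs, host_d)
      q_host <- qs + leak_of(p_tee)
      q_other <- q_tot - q_host
      p_left <- p_tee + fric(q_host, host_d, lengths$tee) +
        accel(q_host, d_mpv, host_d)
      p_right <- fric(q_other, other_d, other_l) +
        accel(q_other, d_mpv, other_d) + r_other * q_other
      p_left - p_right
    }
    qs <- bisect(resid, 0, q_tot)
    p_tee <- shunt_loss(qs, host_d)
    q_host <- qs + leak_of(p_tee)
    p_bif <- p_tee + fric(q_host, host_d, lengths$tee) +
      accel(q_host, d_mpv, host_d)
    p_mid <- p_bif + fric(q_tot, d_mpv, lengths$mpv / 2)
  }
  list(q_shunt = qs, p_mpv_mid = p_mid,
       v_shunt = qs / area(shunt_d), q_total = q_tot)
}
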