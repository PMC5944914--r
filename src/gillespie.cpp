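#include <Rcpp.h>
using namespace Rcpp;

// Exact (Gillespie) stochastic simulation cores for the ant-cargo system.
// All randomness flows through R's RNG so that set.seed() in the calling R
// code makes runs exactly reproducible.

static inline double runif_pos() {
  double u;
  do { u = unif_rand(); } while (u <= 0.0);
  return u;
}

static inline double clamp_exp(double z) {
  // role-switch exponents saturate; guards overflow far outside the
  // physical regime without affecting it
  if (z > 50.0) z = 50.0;
  if (z < -50.0) z = -50.0;
  return std::exp(z);
}

// puller probability under role-switching equilibrium at projection `proj`
static inline double puller_prob(double proj, double F_ind) {
  return 1.0 / (1.0 + clamp_exp(-2.0 * proj / F_ind));
}

// ---------------------------------------------------------------------------
// 1D cargo: front/back pools of binding sites on a point cargo
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
List gillespie1d_cpp(int scheme, List params, double T, double record_dt,
                     double x0, bool freeze_position, bool tanh_restoring,
                     double eps, IntegerVector init_state, double max_events) {
  const double f0 = params["f0"], F_ind = params["F_ind"],
               gamma = params["gamma"], G = params["G"], k_c = params["k_c"];
  const int n_max = (int)Rf_asReal(params["n_max"]);
  const double k_on  = scheme >= 2 ? Rf_asReal(params["k_on"])  : 0.0;
  const double k_off = scheme >= 2 ? Rf_asReal(params["k_off"]) : 0.0;
  const double k_forget = scheme == 3 ? Rf_asReal(params["k_forget"]) : 0.0;

  const int cap_f = (n_max + 1) / 2, cap_b = n_max / 2;

  // state: puller/lifter/informed counts per side
  int npf, npb, nlf, nlb, nif_, nib;
  if (init_state.size() == 6) {
    npf = init_state[0]; npb = init_state[1];
    nlf = init_state[2]; nlb = init_state[3];
    nif_ = init_state[4]; nib = init_state[5];
  } else {
    // default: target means, roles split at the zero-force equilibrium
    int n_u = scheme == 1 ? n_max : (int)std::lround(Rf_asReal(params["n_tot"]));
    int n_i = scheme == 3 ? (int)std::lround(G) : 0;
    npf = npb = nlf = nlb = nif_ = nib = 0;
    int uf = n_u / 2, ub = n_u - n_u / 2;
    for (int i = 0; i < uf; i++) { if (unif_rand() < 0.5) npf++; else nlf++; }
    for (int i = 0; i < ub; i++) { if (unif_rand() < 0.5) npb++; else nlb++; }
    nif_ = n_i / 2; nib = n_i - n_i / 2;
  }

  double x = x0, t = 0.0;
  auto s_of_x = [&](double xx) {
    if (tanh_restoring) return std::tanh(xx / eps);
    return (double)((xx > 0) - (xx < 0));
  };
  auto force = [&]() {
    double Geff = scheme == 3 ? (double)(nif_ + nib) : G;
    return f0 * ((double)(npf - npb) - Geff * s_of_x(x));
  };

  double f_tot = force(), v = f_tot / gamma;

  // recording on a uniform grid (record_dt > 0) or at every event
  std::vector<double> rec;
  const bool grid_rec = record_dt > 0;
  double next_rec = 0.0;
  auto push_rec = [&](double tt, double xx) {
    rec.push_back(tt); rec.push_back(xx); rec.push_back(v);
    rec.push_back(npf); rec.push_back(npb);
    rec.push_back(nlf); rec.push_back(nlb);
    rec.push_back(nif_ + nib);
  };
  if (grid_rec) { push_rec(0.0, x); next_rec = record_dt; }
  else push_rec(0.0, x);

  std::vector<double> event_counts(4, 0.0); // att, det, dec, forget
  double n_events = 0;
  bool absorbed = false;

  while (t < T && n_events < max_events) {
    double phi = f_tot / F_ind;
    double ep = clamp_exp(phi), em = clamp_exp(-phi);
    int n_u = npf + npb + nlf + nlb;
    int n_empty = n_max - n_u - nif_ - nib;

    double R_att = k_on * n_empty;
    double R_det = k_off * n_u;
    double r_lf = k_c * nlf * ep, r_pf = k_c * npf * em;
    double r_lb = k_c * nlb * em, r_pb = k_c * npb * ep;
    double R_dec = r_lf + r_pf + r_lb + r_pb;
    double R_forget = k_forget * (nif_ + nib);
    double R_tot = R_att + R_det + R_dec + R_forget;
    if (R_tot <= 0) { absorbed = true; break; }

    double dt = std::log(1.0 / runif_pos()) / R_tot;
    double t_new = t + dt;

    // emit grid records with the pre-event velocity
    if (grid_rec) {
      while (next_rec <= t_new && next_rec <= T) {
        double xr = freeze_position ? x : x + v * (next_rec - t);
        push_rec(next_rec, xr);
        next_rec += record_dt;
      }
    }
    if (t_new > T) { if (!freeze_position) x += v * (T - t); t = T; break; }

    // advance position, then apply the event
    if (!freeze_position) x += v * dt;
    t = t_new;

    double u2 = unif_rand() * R_tot;
    if (u2 < R_att) {
      // attachment: side uniform among sides with free capacity
      event_counts[0]++;
      int free_f = cap_f - (npf + nlf + nif_), free_b = cap_b - (npb + nlb + nib);
      int side; // +1 front, -1 back
      if (free_f > 0 && free_b > 0) side = unif_rand() < 0.5 ? 1 : -1;
      else side = free_f > 0 ? 1 : -1;
      if (scheme == 3) { if (side == 1) nif_++; else nib++; }
      else {
        double pp = puller_prob(f_tot * side, F_ind);
        if (side == 1) { if (unif_rand() < pp) npf++; else nlf++; }
        else           { if (unif_rand() < pp) npb++; else nlb++; }
      }
    } else if (u2 < R_att + R_det) {
      // detachment of an uninformed ant: side ~ occupancy, role by the
      // role-switching-equilibrium rule
      event_counts[1]++;
      int uf = npf + nlf, ub = npb + nlb;
      int side = (unif_rand() * (uf + ub) < uf) ? 1 : -1;
      double pp = puller_prob(f_tot * side, F_ind);
      bool puller = unif_rand() < pp;
      if (side == 1) {
        if (puller ? npf == 0 : nlf == 0) puller = !puller; // fallback
        if (puller) npf--; else nlf--;
      } else {
        if (puller ? npb == 0 : nlb == 0) puller = !puller;
        if (puller) npb--; else nlb--;
      }
    } else if (u2 < R_att + R_det + R_dec) {
      // role switch, channel ~ its rate
      event_counts[2]++;
      double u3 = unif_rand() * R_dec;
      if (u3 < r_lf) { nlf--; npf++; }
      else if (u3 < r_lf + r_pf) { npf--; nlf++; }
      else if (u3 < r_lf + r_pf + r_lb) { nlb--; npb++; }
      else { npb--; nlb++; }
    } else {
      // informed ant forgets: becomes uninformed on its side
      event_counts[3]++;
      int side = (unif_rand() * (nif_ + nib) < nif_) ? 1 : -1;
      double pp = puller_prob(f_tot * side, F_ind);
      if (side == 1) { nif_--; if (unif_rand() < pp) npf++; else nlf++; }
      else           { nib--;  if (unif_rand() < pp) npb++; else nlb++; }
    }

    f_tot = force();
    v = f_tot / gamma;
    n_events++;
    if (!grid_rec) push_rec(t, x);
  }

  int ncol = 8, nrow = rec.size() / ncol;
  NumericMatrix m(nrow, ncol);
  for (int i = 0; i < nrow; i++)
    for (int j = 0; j < ncol; j++) m(i, j) = rec[i * ncol + j];
  colnames(m) = CharacterVector::create("t", "x", "v", "n_p_front", "n_p_back",
                                        "n_l_front", "n_l_back", "n_inf");
  return List::create(_["records"] = m,
                      _["final"] = NumericVector::create(
                        _["t"] = t, _["x"] = x, _["v"] = v,
                        _["n_p_front"] = npf, _["n_p_back"] = npb,
                        _["n_l_front"] = nlf, _["n_l_back"] = nlb,
                        _["n_inf"] = nif_ + nib),
                      _["event_counts"] = NumericVector::create(
                        _["attach"] = event_counts[0], _["detach"] = event_counts[1],
                        _["switch"] = event_counts[2], _["forget"] = event_counts[3]),
                      _["n_events"] = n_events,
                      _["absorbed"] = absorbed);
}

// ---------------------------------------------------------------------------
// 2D ring cargo carried along a wall (y = 0) with an opening at the origin
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
List gillespie2d_cpp(List params, double T, double record_dt,
                     double x0, double y0, double max_events) {
  const double f0 = params["f0"], F_ind = params["F_ind"],
               gamma = params["gamma"], k_c = params["k_c"],
               k_on = params["k_on"], k_off = params["k_off"],
               k_forget = params["k_forget"], k_orient = params["k_orient"],
               r = params["r"];
  const int n_max = (int)Rf_asReal(params["n_max"]);
  const double n_tot0 = params["n_tot"], G0 = params["G"];

  // site occupancy: 0 empty, 1 puller, 2 lifter, 3 informed
  std::vector<int> occ(n_max, 0);
  std::vector<double> px(n_max), py(n_max), ang(n_max);
  for (int i = 0; i < n_max; i++) {
    ang[i] = 2.0 * M_PI * i / n_max;
    px[i] = std::cos(ang[i]); py[i] = std::sin(ang[i]); // outward radial
  }
  {
    // initial population near the stationary means
    int n_u = std::min((int)std::lround(n_tot0), n_max);
    int n_i = std::min((int)std::lround(G0), n_max - n_u);
    IntegerVector idx = sample(n_max, n_u + n_i, false) - 1;
    for (int k = 0; k < n_u; k++) occ[idx[k]] = unif_rand() < 0.5 ? 1 : 2;
    for (int k = n_u; k < n_u + n_i; k++) occ[idx[k]] = 3;
  }

  double x = x0, y = y0 < r ? r : y0, t = 0.0;
  double fx = 0, fy = 0, vx = 0, vy = 0;

  auto recompute_force = [&]() {
    fx = 0; fy = 0;
    int ninf = 0;
    for (int i = 0; i < n_max; i++) {
      if (occ[i] == 1) { fx += px[i]; fy += py[i]; }
      else if (occ[i] == 3) ninf++;
    }
    double nrm = std::sqrt(x * x + y * y);
    if (nrm > 0) { fx += -ninf * x / nrm; fy += -ninf * y / nrm; }
    fx *= f0; fy *= f0;
    vx = fx / gamma; vy = fy / gamma;
    if (y <= r + 1e-12 && vy < 0) vy = 0; // sliding contact with the wall
  };
  recompute_force();

  std::vector<double> rec;
  double next_rec = 0.0;
  const double rdt = record_dt > 0 ? record_dt : 0.1;
  auto counts = [&](int &np, int &nl, int &ni, int &ne) {
    np = nl = ni = ne = 0;
    for (int i = 0; i < n_max; i++) {
      if (occ[i] == 1) np++; else if (occ[i] == 2) nl++;
      else if (occ[i] == 3) ni++; else ne++;
    }
  };
  auto push_rec = [&](double tt, double xx, double yy) {
    int np, nl, ni, ne; counts(np, nl, ni, ne);
    rec.push_back(tt); rec.push_back(xx); rec.push_back(yy);
    rec.push_back(vx); rec.push_back(vy);
    rec.push_back(np); rec.push_back(nl); rec.push_back(ni);
  };
  push_rec(0.0, x, y);
  next_rec = rdt;

  std::vector<double> site_rate(n_max, 0.0);
  std::vector<double> event_counts(5, 0.0);
  double n_events = 0;

  while (t < T && n_events < max_events) {
    int np, nl, ni, ne; counts(np, nl, ni, ne);
    double R_att = k_on * ne, R_det = k_off * (np + nl);
    double R_dec = 0;
    for (int i = 0; i < n_max; i++) {
      if (occ[i] == 1)
        site_rate[i] = k_c * clamp_exp(-(fx * px[i] + fy * py[i]) / F_ind);
      else if (occ[i] == 2)
        site_rate[i] = k_c * clamp_exp((fx * px[i] + fy * py[i]) / F_ind);
      else site_rate[i] = 0.0;
      R_dec += site_rate[i];
    }
    double R_forget = k_forget * ni, R_orient = k_orient * np;
    double R_tot = R_att + R_det + R_dec + R_forget + R_orient;
    if (R_tot <= 0) break;

    double dt = std::log(1.0 / runif_pos()) / R_tot;
    double t_new = t + dt;

    while (next_rec <= t_new && next_rec <= T) {
      double dd = next_rec - t;
      double xr = x + vx * dd, yr = y + vy * dd;
      if (yr < r) yr = r;
      push_rec(next_rec, xr, yr);
      next_rec += rdt;
    }
    if (t_new > T) {
      x += vx * (T - t); y += vy * (T - t); if (y < r) y = r;
      t = T; break;
    }

    x += vx * dt; y += vy * dt;
    if (y < r) y = r; // wall: zero the normal part of the displacement
    t = t_new;

    double u2 = unif_rand() * R_tot;
    if (u2 < R_att) {
      event_counts[0]++;
      int pick = (int)(unif_rand() * ne), j = -1;
      for (int i = 0; i < n_max; i++) if (occ[i] == 0 && ++j == pick) {
        occ[i] = 3; px[i] = std::cos(ang[i]); py[i] = std::sin(ang[i]);
        break;
      }
    } else if (u2 < R_att + R_det) {
      event_counts[1]++;
      int pick = (int)(unif_rand() * (np + nl)), j = -1;
      for (int i = 0; i < n_max; i++)
        if ((occ[i] == 1 || occ[i] == 2) && ++j == pick) { occ[i] = 0; break; }
    } else if (u2 < R_att + R_det + R_dec) {
      event_counts[2]++;
      double u3 = unif_rand() * R_dec, acc = 0;
      for (int i = 0; i < n_max; i++) {
        acc += site_rate[i];
        if (u3 < acc) { occ[i] = occ[i] == 1 ? 2 : 1; break; }
      }
    } else if (u2 < R_att + R_det + R_dec + R_forget) {
      event_counts[3]++;
      int pick = (int)(unif_rand() * ni), j = -1;
      for (int i = 0; i < n_max; i++) if (occ[i] == 3 && ++j == pick) {
        double proj = fx * px[i] + fy * py[i];
        occ[i] = unif_rand() < puller_prob(proj, F_ind) ? 1 : 2;
        break;
      }
    } else {
      // re-orientation toward the direction of motion: at the wall the
      // constrained velocity is tangential, which channels the pullers'
      // alignment along the obstacle (the total force coincides with the
      // motion away from the wall, but not at contact)
      event_counts[4]++;
      int pick = (int)(unif_rand() * np), j = -1;
      double vn = std::sqrt(vx * vx + vy * vy);
      for (int i = 0; i < n_max; i++) if (occ[i] == 1 && ++j == pick) {
        if (vn > 0) { px[i] = vx / vn; py[i] = vy / vn; } // no-op if at rest
        break;
      }
    }

    recompute_force();
    n_events++;
  }

  int ncol = 8, nrow = rec.size() / ncol;
  NumericMatrix m(nrow, ncol);
  for (int i = 0; i < nrow; i++)
    for (int j = 0; j < ncol; j++) m(i, j) = rec[i * ncol + j];
  colnames(m) = CharacterVector::create("t", "x", "y", "vx", "vy",
                                        "n_p", "n_l", "n_inf");
  return List::create(_["records"] = m,
                      _["event_counts"] = NumericVector::create(
                        _["attach"] = event_counts[0], _["detach"] = event_counts[1],
                        _["switch"] = event_counts[2], _["forget"] = event_counts[3],
                        _["orient"] = event_counts[4]),
                      _["n_events"] = n_events,
                      _["final_t"] = t);
}
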