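// Core stepping loop of the dynein-crosslinked microtubule bundle
// simulation. Filaments are rigid rods of fixed length on a hexagonal
// lattice of lines parallel to the axon axis; lattice-adjacent filaments
// with x-overlap are coupled by motors with a linear force-velocity
// relation; per-step velocities come from a force balance (motor drive +
// motor coupling + viscous drag + boundary forces = 0), a symmetric
// positive-definite linear system.

#include <RcppArmadillo.h>
#include <map>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

namespace {

struct Params {
  double chi, lambda, l_mt, xi, f_stall, v0, dt;
  double left_spring, exit_rate, right_force;
  bool templating, unbounded, random_glide;
  double p_plus_amp, p_minus_amp, p_decay;
  int n_lines;
};

Params read_params(const List& cfg) {
  Params p;
  p.chi = cfg["chi"];
  p.lambda = cfg["lambda_m"];
  p.l_mt = cfg["l_mt"];
  p.xi = cfg["xi"];
  p.f_stall = cfg["f_stall"];
  p.v0 = cfg["v0"];
  p.dt = cfg["dt"];
  p.left_spring = cfg["left_spring"];
  p.exit_rate = cfg["exit_rate"];
  p.right_force = cfg["right_force"];
  p.templating = cfg["use_templating"];
  p.unbounded = cfg["use_unbounded"];
  p.random_glide = cfg["random_gliding"];
  p.p_plus_amp = cfg["p_plus_amp"];
  p.p_minus_amp = cfg["p_minus_amp"];
  p.p_decay = cfg["p_decay"];
  p.n_lines = cfg["n_lines"];
  return p;
}

struct Bundle {
  std::vector<double> x;   // centre positions (um)
  std::vector<int> orient; // +1 plus-end distal, -1 plus-end proximal
  std::vector<int> line;   // lattice line index (0-based)
  std::vector<int> id;     // stable filament id
};

double tip_pos(const Bundle& b, double half) {
  double m = 0.0;
  for (size_t i = 0; i < b.x.size(); ++i) m = std::max(m, b.x[i] + half);
  return m;
}

// velocities from the force balance; optionally resolves the constant
// distal-boundary force in a second pass restricted to tip-contacting
// filaments that move outward in the first pass
arma::vec solve_velocities(const Bundle& b, const IntegerMatrix& adj,
                           const Params& p,
                           std::map<std::pair<int, int>, int>* glide_sign) {
  int n = (int)b.x.size();
  arma::vec v(n, arma::fill::zeros);
  if (n == 0) return v;
  double half = p.l_mt / 2.0;
  arma::mat A(n, n, arma::fill::zeros);
  arma::vec F(n, arma::fill::zeros);
  for (int i = 0; i < n; ++i) A(i, i) = p.xi * p.l_mt;
  for (int i = 0; i < n; ++i) {
    for (int j = i + 1; j < n; ++j) {
      if (b.line[i] == b.line[j]) continue;
      if (!adj(b.line[i], b.line[j])) continue;
      double ov = std::min(b.x[i] + half, b.x[j] + half) -
                  std::max(b.x[i] - half, b.x[j] - half);
      if (ov <= 0) continue;
      double nm = p.chi * p.lambda * ov; // motors in the overlap
      double c = nm * p.f_stall / (2.0 * p.v0);
      A(i, i) += c;
      A(j, j) += c;
      A(i, j) -= c;
      A(j, i) -= c;
      if (p.random_glide) {
        // motors on this overlap glide in a random, contact-persistent
        // direction (no dynein directionality)
        std::pair<int, int> key(std::min(b.id[i], b.id[j]),
                                std::max(b.id[i], b.id[j]));
        int s;
        auto it = glide_sign->find(key);
        if (it == glide_sign->end()) {
          s = (unif_rand() < 0.5) ? 1 : -1;
          (*glide_sign)[key] = s;
        } else {
          s = it->second;
        }
        F(i) += nm * p.f_stall * s;
        F(j) -= nm * p.f_stall * s;
      } else if (b.orient[i] != b.orient[j]) {
        // antiparallel pair: dynein drives each filament toward its own
        // plus end (minus-end-out filaments move proximally)
        F(i) += nm * p.f_stall * b.orient[i];
        F(j) += nm * p.f_stall * b.orient[j];
      }
      // parallel pair with directional motors: drives cancel, motors act
      // as velocity coupling only
    }
  }
  // leaky-spring left boundary at x = 0
  for (int i = 0; i < n; ++i) {
    double pen = -(b.x[i] - half);
    if (pen > 0) F(i) += p.left_spring * pen;
  }
  v = arma::solve(A, F, arma::solve_opts::likely_sympd);
  if (p.right_force <= 0) return v;
  // distal boundary: the membrane resists outgrowth of tip-contacting
  // filaments with up to `right_force` pN in total. While the force
  // needed to stall the contacts stays below the budget, contacts are
  // held at zero velocity (constrained solve); once the demanded holding
  // force exceeds the budget the boundary yields and the constant total
  // force is distributed over the contacts in proportion to their push.
  double tip = tip_pos(b, half);
  double tol = p.v0 * p.dt;
  std::vector<bool> contact(n, false);
  bool any_contact = false;
  for (int i = 0; i < n; ++i) {
    if (b.x[i] + half >= tip - tol && v(i) > 1e-12) {
      contact[i] = true;
      any_contact = true;
    }
  }
  if (!any_contact) return v;
  arma::vec wall(n, arma::fill::zeros);
  for (int iter = 0; iter < 8; ++iter) {
    // constrained solve: v = 0 on the contact set
    std::vector<int> freeIdx;
    for (int i = 0; i < n; ++i)
      if (!contact[i]) freeIdx.push_back(i);
    arma::vec vc(n, arma::fill::zeros);
    if (!freeIdx.empty()) {
      arma::uvec fi(freeIdx.size());
      for (size_t k = 0; k < freeIdx.size(); ++k) fi(k) = freeIdx[k];
      arma::vec vf = arma::solve(A.submat(fi, fi), F(fi),
                                 arma::solve_opts::likely_sympd);
      for (size_t k = 0; k < freeIdx.size(); ++k) vc(freeIdx[k]) = vf(k);
    }
    // wall force needed to hold each contact: w_i = A v - F (inward < 0)
    wall = A * vc - F;
    bool changed = false;
    for (int i = 0; i < n; ++i) {
      if (contact[i] && wall(i) > 1e-9) {
        contact[i] = false; // wall would have to pull: release
        changed = true;
      }
    }
    if (!changed) {
      v = vc;
      break;
    }
    any_contact = false;
    for (int i = 0; i < n; ++i) any_contact = any_contact || contact[i];
    if (!any_contact) return v; // nothing actually pushes: first solve holds
  }
  double demand = 0.0;
  for (int i = 0; i < n; ++i) {
    if (contact[i]) demand += -wall(i);
  }
  if (demand > p.right_force) {
    // boundary yields: constant total force, split in proportion to push
    arma::vec F2 = F;
    for (int i = 0; i < n; ++i) {
      if (contact[i]) F2(i) -= p.right_force * (-wall(i)) / demand;
    }
    v = arma::solve(A, F2, arma::solve_opts::likely_sympd);
  }
  return v;
}

// fraction of plus-end-out filaments whose x-interval covers xc;
// -1 when no filament covers it
double local_plus_fraction(const Bundle& b, double xc, double half) {
  int n_tot = 0, n_plus = 0;
  for (size_t i = 0; i < b.x.size(); ++i) {
    if (std::fabs(b.x[i] - xc) <= half) {
      ++n_tot;
      if (b.orient[i] == 1) ++n_plus;
    }
  }
  if (n_tot == 0) return -1.0;
  return (double)n_plus / (double)n_tot;
}

bool line_free(const Bundle& b, int line, double xc, double l_mt) {
  for (size_t i = 0; i < b.x.size(); ++i) {
    if (b.line[i] == line && std::fabs(b.x[i] - xc) < l_mt) return false;
  }
  return true;
}

} // namespace

// [[Rcpp::export]]
NumericVector bundle_velocities_cpp(NumericVector x, IntegerVector orient,
                                    IntegerVector line, IntegerMatrix adj,
                                    List cfg) {
  Params p = read_params(cfg);
  Bundle b;
  b.x = as<std::vector<double>>(x);
  b.orient = as<std::vector<int>>(orient);
  b.line = as<std::vector<int>>(line);
  b.id.resize(b.x.size());
  for (size_t i = 0; i < b.id.size(); ++i) b.id[i] = (int)i;
  std::map<std::pair<int, int>, int> glide;
  arma::vec v = solve_velocities(b, adj, p, &glide);
  return wrap(std::vector<double>(v.begin(), v.end()));
}

// [[Rcpp::export]]
List bundle_run_cpp(NumericVector x0, IntegerVector orient0,
                    IntegerVector line0, IntegerMatrix adj, List cfg,
                    int n_steps, double addition_interval,
                    int snapshot_every) {
  Params p = read_params(cfg);
  double half = p.l_mt / 2.0;
  Bundle b;
  b.x = as<std::vector<double>>(x0);
  b.orient = as<std::vector<int>>(orient0);
  b.line = as<std::vector<int>>(line0);
  int next_id = (int)b.x.size();
  b.id.resize(b.x.size());
  for (size_t i = 0; i < b.id.size(); ++i) b.id[i] = (int)i;

  std::map<std::pair<int, int>, int> glide;

  // snapshots
  std::vector<double> sn_t, sn_x;
  std::vector<int> sn_id, sn_or, sn_line;
  // event log
  std::vector<double> ev_t, ev_x;
  std::vector<int> ev_type, ev_id, ev_or; // 1 add, 2 exit, 3 add rejected, 4 add skipped (no space)
  std::vector<double> len_t, len_val;

  double next_add = addition_interval;
  auto snapshot = [&](double t) {
    for (size_t i = 0; i < b.x.size(); ++i) {
      sn_t.push_back(t);
      sn_id.push_back(b.id[i]);
      sn_x.push_back(b.x[i]);
      sn_or.push_back(b.orient[i]);
      sn_line.push_back(b.line[i]);
    }
  };
  snapshot(0.0);
  len_t.push_back(0.0);
  len_val.push_back(tip_pos(b, half));

  for (int step = 1; step <= n_steps; ++step) {
    double t = step * p.dt;
    // (i-iv) force balance and position update
    arma::vec v = solve_velocities(b, adj, p, &glide);
    for (size_t i = 0; i < b.x.size(); ++i) b.x[i] += v(i) * p.dt;
    // (v) exits at the leaky left boundary
    for (int i = (int)b.x.size() - 1; i >= 0; --i) {
      if (b.x[i] - half < 0 && unif_rand() < p.exit_rate * p.dt) {
        ev_t.push_back(t);
        ev_type.push_back(2);
        ev_id.push_back(b.id[i]);
        ev_x.push_back(b.x[i]);
        ev_or.push_back(b.orient[i]);
        b.x.erase(b.x.begin() + i);
        b.orient.erase(b.orient.begin() + i);
        b.line.erase(b.line.begin() + i);
        b.id.erase(b.id.begin() + i);
      }
    }
    // MT addition on a deterministic timer
    while (t >= next_add) {
      next_add += addition_interval;
      double axon_len = std::max(tip_pos(b, half), 6.0);
      double xc = unif_rand() * axon_len;
      // orientation: templating or 50/50
      int ori;
      if (p.templating) {
        double pf = local_plus_fraction(b, xc, half);
        if (pf < 0) pf = 0.5;
        ori = (unif_rand() < pf) ? 1 : -1;
      } else {
        ori = (unif_rand() < 0.5) ? 1 : -1;
      }
      // unbounded-growth gate: nucleation succeeds only with the
      // orientation- and position-dependent likelihood
      bool accept = true;
      if (p.unbounded) {
        double dist = std::max(0.0, tip_pos(b, half) - xc);
        double amp = (ori == 1) ? p.p_plus_amp : p.p_minus_amp;
        double like = amp * std::exp(-dist / p.p_decay);
        if (unif_rand() >= like) accept = false;
      }
      if (!accept) {
        ev_t.push_back(t);
        ev_type.push_back(3);
        ev_id.push_back(-1);
        ev_x.push_back(xc);
        ev_or.push_back(ori);
        continue;
      }
      // lattice placement without same-line overlap; bounded retries with
      // fresh x each time
      bool placed = false;
      for (int attempt = 0; attempt < 30 && !placed; ++attempt) {
        int ln = (int)std::floor(unif_rand() * p.n_lines);
        if (ln >= p.n_lines) ln = p.n_lines - 1;
        if (line_free(b, ln, xc, p.l_mt)) {
          b.x.push_back(xc);
          b.orient.push_back(ori);
          b.line.push_back(ln);
          b.id.push_back(next_id);
          ev_t.push_back(t);
          ev_type.push_back(1);
          ev_id.push_back(next_id);
          ev_x.push_back(xc);
          ev_or.push_back(ori);
          ++next_id;
          placed = true;
        } else {
          xc = unif_rand() * axon_len;
        }
      }
      if (!placed) {
        ev_t.push_back(t);
        ev_type.push_back(4);
        ev_id.push_back(-1);
        ev_x.push_back(xc);
        ev_or.push_back(ori);
      }
    }
    if (step % snapshot_every == 0 || step == n_steps) {
      snapshot(t);
      len_t.push_back(t);
      len_val.push_back(tip_pos(b, half));
    }
  }

  return List::create(
      _["snapshots"] = DataFrame::create(
          _["time_s"] = sn_t, _["mt_id"] = sn_id, _["x_center_um"] = sn_x,
          _["orientation"] = sn_or, _["lattice_line"] = sn_line),
      _["events"] = DataFrame::create(
          _["time_s"] = ev_t, _["type"] = ev_type, _["mt_id"] = ev_id,
          _["x_um"] = ev_x, _["orientation"] = ev_or),
      _["length"] = DataFrame::create(_["time_s"] = len_t,
                                      _["axon_length_um"] = len_val),
      _["final"] = List::create(
          _["x"] = wrap(b.x), _["orientation"] = wrap(b.orient),
          _["lattice_line"] = wrap(b.line), _["mt_id"] = wrap(b.id)));
}
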