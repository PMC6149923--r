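#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// Per-cell state codes: 0 = quiescent, 1 = cycling, 2 = apoptotic.
// Phase codes used in snapshots: 0 G0G1, 1 S, 2 G2, 3 M, 4 quiescent, 5 apoptotic.

namespace {

struct Offsets {
  std::vector<int> dx, dy, dz;
  std::vector<double> r_um;
};

Offsets manhattan_ball(int radius, double spacing) {
  Offsets o;
  for (int dx = -radius; dx <= radius; ++dx)
    for (int dy = -radius; dy <= radius; ++dy)
      for (int dz = -radius; dz <= radius; ++dz) {
        int m = std::abs(dx) + std::abs(dy) + std::abs(dz);
        if (m == 0 || m > radius) continue;
        o.dx.push_back(dx);
        o.dy.push_back(dy);
        o.dz.push_back(dz);
        o.r_um.push_back(spacing * std::sqrt((double)(dx * dx + dy * dy + dz * dz)));
      }
  return o;
}

const int FX[6] = {1, -1, 0, 0, 0, 0};
const int FY[6] = {0, 0, 1, -1, 0, 0};
const int FZ[6] = {0, 0, 0, 0, 1, -1};

inline double pref_weight(int n_nb) {
  if (n_nb >= 5) return 0.125;
  if (n_nb >= 3) return 0.25;
  if (n_nb >= 1) return 1.0;
  return 0.0625;
}

} // namespace

// [[Rcpp::export]]
List cpp_run_simulation(IntegerMatrix init_xyz, NumericVector init_age_h,
                        int n_per_axis, double spacing_um, int horizon_steps,
                        double dt_h, double lambda, double c1, double c2,
                        NumericVector theta, double p_pro,
                        IntegerVector schedule, int apoptosis_steps,
                        double d1_0, double half_life1, double d2_0,
                        double half_life2, double motility_D,
                        double kernel_dt_h, int division_radius,
                        IntegerVector snapshot_steps,
                        bool init_cycle_from_age) {
  const int n = n_per_axis;
  const long nsites = (long)n * n * n;
  std::vector<int> occ(nsites, 0); // cell index + 1, 0 = empty

  const int cycle_total = schedule[0] + schedule[1] + schedule[2] + schedule[3];
  const int m_start = cycle_total - schedule[3]; // cpos > m_start => M phase

  std::vector<int> cx, cy, cz, state, cpos, countdown;
  std::vector<double> age;
  std::vector<bool> alive;

  int n0 = init_xyz.nrow();
  cx.reserve(4 * n0); cy.reserve(4 * n0); cz.reserve(4 * n0);
  for (int i = 0; i < n0; ++i) {
    int x = init_xyz(i, 0), y = init_xyz(i, 1), z = init_xyz(i, 2);
    if (x < 0 || y < 0 || z < 0 || x >= n || y >= n || z >= n)
      stop("initial cell outside the lattice");
    long s = ((long)x * n + y) * n + z;
    if (occ[s] != 0) stop("two initial cells on one site");
    occ[s] = i + 1;
    cx.push_back(x); cy.push_back(y); cz.push_back(z);
    // seeding cycle position from the random initial age desynchronises
    // the first division wave
    if (init_cycle_from_age) {
      state.push_back(1);
      cpos.push_back((int)std::floor(init_age_h[i] / dt_h) % cycle_total);
    } else {
      state.push_back(0);
      cpos.push_back(0);
    }
    countdown.push_back(0);
    age.push_back(init_age_h[i]); alive.push_back(true);
  }

  Offsets mig = manhattan_ball(1, spacing_um);
  Offsets div = manhattan_ball(division_radius, spacing_um);
  const double kernel_s = 4.0 * M_PI * motility_D * kernel_dt_h;

  auto site_of = [n](int x, int y, int z) { return ((long)x * n + y) * n + z; };
  auto occupied = [&](int x, int y, int z) {
    if (x < 0 || y < 0 || z < 0 || x >= n || y >= n || z >= n) return false;
    return occ[site_of(x, y, z)] != 0;
  };
  // occupied face neighbours of (x,y,z), the mover's own site excluded
  auto count_neighbors = [&](int x, int y, int z, int ex, int ey, int ez) {
    int cnt = 0;
    for (int f = 0; f < 6; ++f) {
      int nx = x + FX[f], ny = y + FY[f], nz = z + FZ[f];
      if (nx == ex && ny == ey && nz == ez) continue;
      if (occupied(nx, ny, nz)) ++cnt;
    }
    return cnt;
  };

  // roulette selection over the free sites of an offset set; returns the
  // linear site index of the chosen free site, or -1 if none is free
  auto pick_free_site = [&](int i, const Offsets &off) -> long {
    int x0 = cx[i], y0 = cy[i], z0 = cz[i];
    std::vector<long> sites;
    std::vector<double> w;
    double total = 0.0;
    for (size_t l = 0; l < off.dx.size(); ++l) {
      int x = x0 + off.dx[l], y = y0 + off.dy[l], z = z0 + off.dz[l];
      if (x < 0 || y < 0 || z < 0 || x >= n || y >= n || z >= n) continue;
      long s = site_of(x, y, z);
      if (occ[s] != 0) continue;
      int nb = count_neighbors(x, y, z, x0, y0, z0);
      double r = off.r_um[l];
      double rank = 0.25 * (1.0 / kernel_s) * std::exp(-r * r / kernel_s) *
                    pref_weight(nb);
      sites.push_back(s);
      w.push_back(rank);
      total += rank;
    }
    if (sites.empty()) return -1;
    double d = unif_rand() * total;
    double cum = 0.0;
    for (size_t l = 0; l < sites.size(); ++l) {
      cum += w[l];
      if (d < cum) return sites[l];
    }
    return sites.back();
  };

  // trajectory: step, time_h, n_total, n_alive, n_quiescent, n_apoptotic,
  // drug1, drug2, births, removals
  NumericMatrix traj(horizon_steps + 1, 10);
  auto record = [&](int step, double t, double d1, double d2, int births,
                    int removals) {
    int ntot = 0, nq = 0, nap = 0;
    for (size_t i = 0; i < alive.size(); ++i) {
      if (!alive[i]) continue;
      ++ntot;
      if (state[i] == 2) ++nap;
      else if (state[i] == 0) ++nq;
    }
    traj(step, 0) = step; traj(step, 1) = t;
    traj(step, 2) = ntot; traj(step, 3) = ntot - nap;
    traj(step, 4) = nq;  traj(step, 5) = nap;
    traj(step, 6) = d1;  traj(step, 7) = d2;
    traj(step, 8) = births; traj(step, 9) = removals;
  };

  std::vector<int> snap_step, snap_id, snap_x, snap_y, snap_z, snap_phase;
  std::vector<double> snap_age;
  auto want_snapshot = [&](int step) {
    for (int k = 0; k < snapshot_steps.size(); ++k)
      if (snapshot_steps[k] == step) return true;
    return false;
  };
  auto take_snapshot = [&](int step) {
    for (size_t i = 0; i < alive.size(); ++i) {
      if (!alive[i]) continue;
      int ph;
      if (state[i] == 2) ph = 5;
      else if (state[i] == 0) ph = 4;
      else if (cpos[i] > m_start) ph = 3;
      else if (cpos[i] > schedule[0] + schedule[1]) ph = 2;
      else if (cpos[i] > schedule[0]) ph = 1;
      else ph = 0;
      snap_step.push_back(step); snap_id.push_back((int)i + 1);
      snap_x.push_back(cx[i]); snap_y.push_back(cy[i]); snap_z.push_back(cz[i]);
      snap_phase.push_back(ph); snap_age.push_back(age[i]);
    }
  };

  record(0, 0.0, d1_0, d2_0, 0, 0);
  if (want_snapshot(0)) take_snapshot(0);

  std::vector<int> order;
  for (int step = 1; step <= horizon_steps; ++step) {
    double t = step * dt_h;
    // closed-form decay from t0 each step: no incremental drift
    double d1 = d1_0 * std::pow(0.5, t / half_life1);
    double d2 = d2_0 * std::pow(0.5, t / half_life2);
    double mc = theta[0] + theta[1] * d1 + theta[2] * d2;
    if (mc < 0) mc = 0;
    if (mc > 1) mc = 1;

    order.clear();
    for (size_t i = 0; i < alive.size(); ++i)
      if (alive[i]) order.push_back((int)i);
    // Fisher-Yates shuffle with R's RNG
    for (int k = (int)order.size() - 1; k > 0; --k) {
      int j = (int)std::floor(unif_rand() * (k + 1));
      if (j > k) j = k;
      std::swap(order[k], order[j]);
    }

    int births = 0, removals = 0;

    // Pass A: apoptosis countdowns and decisions
    for (int i : order) {
      if (!alive[i]) continue;
      if (state[i] == 2) {
        if (--countdown[i] <= 0) {
          occ[site_of(cx[i], cy[i], cz[i])] = 0;
          alive[i] = false;
          ++removals;
        }
      } else {
        double mn = age[i] > 0 ? 1.0 - std::exp(-lambda * age[i]) : 0.0;
        if (c1 * mn + c2 * mc > unif_rand()) {
          state[i] = 2;
          countdown[i] = apoptosis_steps;
        }
      }
    }

    // Pass B: proliferation decisions / cycle advance
    for (int i : order) {
      if (!alive[i] || state[i] == 2) continue;
      if (state[i] == 0) {
        if (unif_rand() < p_pro) {
          state[i] = 1;
          cpos[i] = 0;
        }
      } else if (cpos[i] < cycle_total) {
        ++cpos[i];
      }
    }

    // Pass C: division attempts for cells that completed M phase;
    // a blocked cell stays division-ready and retries (Rule 2)
    for (int i : order) {
      if (!alive[i] || state[i] != 1 || cpos[i] < cycle_total) continue;
      long s = pick_free_site(i, div);
      if (s < 0) continue;
      int dxn = (int)(s / ((long)n * n));
      int dyn = (int)((s / n) % n);
      int dzn = (int)(s % n);
      int id = (int)cx.size();
      cx.push_back(dxn); cy.push_back(dyn); cz.push_back(dzn);
      state.push_back(0); cpos.push_back(0); countdown.push_back(0);
      age.push_back(0.0); alive.push_back(true);
      occ[s] = id + 1;
      state[i] = 0; // mother re-tests the proliferation rule next step
      cpos[i] = 0;
      ++births;
    }

    // Pass D: migration of every live non-apoptotic, non-M-phase cell;
    // a fully enclosed cell becomes reversibly quiescent (Rule 2)
    for (int i : order) {
      if (!alive[i] || state[i] == 2) continue;
      if (state[i] == 1 && cpos[i] > m_start) continue; // M phase: divide only
      long s = pick_free_site(i, mig);
      if (s < 0) {
        state[i] = 0;
        cpos[i] = 0;
        continue;
      }
      occ[site_of(cx[i], cy[i], cz[i])] = 0;
      cx[i] = (int)(s / ((long)n * n));
      cy[i] = (int)((s / n) % n);
      cz[i] = (int)(s % n);
      occ[s] = i + 1;
    }

    for (size_t i = 0; i < alive.size(); ++i)
      if (alive[i]) age[i] += dt_h;

    record(step, t, d1, d2, births, removals);
    if (want_snapshot(step)) take_snapshot(step);
  }

  // final cell table for audits
  int nfin = 0;
  for (size_t i = 0; i < alive.size(); ++i)
    if (alive[i]) ++nfin;
  IntegerVector fid(nfin), fx(nfin), fy(nfin), fz(nfin), fstate(nfin),
      fcpos(nfin);
  NumericVector fage(nfin);
  int k = 0;
  for (size_t i = 0; i < alive.size(); ++i) {
    if (!alive[i]) continue;
    fid[k] = (int)i + 1; fx[k] = cx[i]; fy[k] = cy[i]; fz[k] = cz[i];
    fstate[k] = state[i]; fcpos[k] = cpos[i]; fage[k] = age[i];
    ++k;
  }

  return List::create(
      _["trajectory"] = traj,
      _["final_cells"] = List::create(_["cell_id"] = fid, _["x"] = fx,
                                      _["y"] = fy, _["z"] = fz,
                                      _["state"] = fstate, _["cycle_position"] = fcpos,
                                      _["age_h"] = fage),
      _["snapshots"] = List::create(
          _["step"] = wrap(snap_step), _["cell_id"] = wrap(snap_id),
          _["x"] = wrap(snap_x), _["y"] = wrap(snap_y), _["z"] = wrap(snap_z),
          _["phase"] = wrap(snap_phase), _["age_h"] = wrap(snap_age)));
}
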