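// Discrete-particle / Markov-transporter simulation core.
//
// All randomness flows through R's RNG (unif_rand / norm_rand), so a single
// set.seed() before a call makes whole runs bit-reproducible. Lengths are in
// nm, times in ms, rates in 1/ms; transition probabilities are per-step
// Bernoulli probabilities (rate * dt) and must stay below 1 per state.

#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// particle status codes
static const int P_FREE = 0;
static const int P_BOUND = 1;
static const int P_GONE = 2; // removed at boundary or translocated

// transition action codes (kept in sync with the R side)
static const int A_NONE = 0;
static const int A_GLU_BIND = 1;
static const int A_GLU_RELEASE_OUT = 2;
static const int A_GLU_RELEASE_IN = 3;
static const int A_GLU_LOAD_IN = 4;
static const int A_CA_BIND_IN = 5;
static const int A_CA_RELEASE_IN = 6;
static const int A_CA_RELEASE_OUT = 7;
static const int A_CA_LOAD_OUT = 8;

// dynamic-ligand codes
static const int D_NONE = 0;
static const int D_GLU_LOCAL = 1;
static const int D_NA_I = 2;
static const int D_NA_I3 = 3;
static const int D_CA_I = 4;

// [[Rcpp::export]]
NumericVector diffuse_free_msd_cpp(int n, double sd_nm, int n_steps) {
  RNGScope scope;
  std::vector<double> x(n, 0.0), y(n, 0.0), z(n, 0.0);
  NumericVector msd(n_steps);
  for (int s = 0; s < n_steps; ++s) {
    double acc = 0.0;
    for (int i = 0; i < n; ++i) {
      x[i] += sd_nm * norm_rand();
      y[i] += sd_nm * norm_rand();
      z[i] += sd_nm * norm_rand();
      acc += x[i] * x[i] + y[i] * y[i] + z[i] * z[i];
    }
    msd[s] = acc / n;
  }
  return msd;
}

struct Grid {
  const int* lab;
  int nx, ny, nz;
  double dx, dy, dz;
  inline int voxel(double x, double y, double z) const {
    int i = (int)std::floor(x / dx);
    int j = (int)std::floor(y / dy);
    int k = (int)std::floor(z / dz);
    if (i < 0 || j < 0 || k < 0 || i >= nx || j >= ny || k >= nz) return -1;
    return lab[i + nx * (j + (long)ny * k)];
  }
};

// One diffusion sweep over a particle set with the compartment-confinement
// and baseline-floor boundary rules. Returns boundary removals.
static int diffuse_sweep(std::vector<double>& px, std::vector<double>& py,
                         std::vector<double>& pz, std::vector<int>& st,
                         const Grid& g, int home, double sd_nm,
                         int baseline, int& free_count) {
  int removed = 0;
  size_t n = px.size();
  for (size_t i = 0; i < n; ++i) {
    if (st[i] != P_FREE) continue;
    double nxp = px[i] + sd_nm * norm_rand();
    double nyp = py[i] + sd_nm * norm_rand();
    double nzp = pz[i] + sd_nm * norm_rand();
    int lab = g.voxel(nxp, nyp, nzp);
    if (lab < 0) {
      // left the sample: remove unless the pool is at/below baseline
      if (free_count > baseline) {
        st[i] = P_GONE;
        --free_count;
        ++removed;
      }
      // else: placed back (position unchanged)
    } else if (lab == home) {
      px[i] = nxp; py[i] = nyp; pz[i] = nzp;
    }
    // different compartment: placed back
  }
  return removed;
}

// [[Rcpp::export]]
List diffuse_pool_cpp(NumericMatrix pos, IntegerVector status,
                      IntegerVector labels, IntegerVector dim,
                      NumericVector pitch, int home_id, double sd_nm,
                      int n_steps, int baseline) {
  RNGScope scope;
  int n = pos.nrow();
  std::vector<double> px(n), py(n), pz(n);
  std::vector<int> st(n);
  for (int i = 0; i < n; ++i) {
    px[i] = pos(i, 0); py[i] = pos(i, 1); pz[i] = pos(i, 2);
    st[i] = status[i];
  }
  Grid g{labels.begin(), dim[0], dim[1], dim[2], pitch[0], pitch[1], pitch[2]};
  int free_count = 0;
  for (int i = 0; i < n; ++i) if (st[i] == P_FREE) ++free_count;
  int removed = 0;
  for (int s = 0; s < n_steps; ++s) {
    removed += diffuse_sweep(px, py, pz, st, g, home_id, sd_nm, baseline,
                             free_count);
  }
  NumericMatrix out(n, 3);
  IntegerVector ost(n);
  for (int i = 0; i < n; ++i) {
    out(i, 0) = px[i]; out(i, 1) = py[i]; out(i, 2) = pz[i];
    ost[i] = st[i];
  }
  return List::create(_["pos"] = out, _["status"] = ost,
                      _["boundary_removed"] = removed);
}

// Volume (nm^3) of the voxels carrying `region_id` inside an axis-aligned
// box of edge `edge_nm` centred at each row of `centers`, clipped at the
// sample boundary; exact axis-aligned overlap.
// [[Rcpp::export]]
NumericVector box_region_volume_cpp(IntegerVector labels, IntegerVector dim,
                                    NumericVector pitch, NumericMatrix centers,
                                    double edge_nm, int region_id) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  double dx = pitch[0], dy = pitch[1], dz = pitch[2];
  const int* lab = labels.begin();
  int m = centers.nrow();
  NumericVector out(m);
  double h = edge_nm / 2.0;
  for (int c = 0; c < m; ++c) {
    double x0 = centers(c, 0) - h, x1 = centers(c, 0) + h;
    double y0 = centers(c, 1) - h, y1 = centers(c, 1) + h;
    double z0 = centers(c, 2) - h, z1 = centers(c, 2) + h;
    int i0 = std::max(0, (int)std::floor(x0 / dx));
    int i1 = std::min(nx - 1, (int)std::floor((x1 - 1e-9) / dx));
    int j0 = std::max(0, (int)std::floor(y0 / dy));
    int j1 = std::min(ny - 1, (int)std::floor((y1 - 1e-9) / dy));
    int k0 = std::max(0, (int)std::floor(z0 / dz));
    int k1 = std::min(nz - 1, (int)std::floor((z1 - 1e-9) / dz));
    double vol = 0.0;
    for (int k = k0; k <= k1; ++k) {
      double oz = std::min(z1, (k + 1) * dz) - std::max(z0, k * dz);
      if (oz <= 0) continue;
      for (int j = j0; j <= j1; ++j) {
        double oy = std::min(y1, (j + 1) * dy) - std::max(y0, j * dy);
        if (oy <= 0) continue;
        for (int i = i0; i <= i1; ++i) {
          if (lab[i + nx * (j + (long)ny * k)] != region_id) continue;
          double ox = std::min(x1, (i + 1) * dx) - std::max(x0, i * dx);
          if (ox > 0) vol += ox * oy * oz;
        }
      }
    }
    out[c] = vol;
  }
  return out;
}

// compiled kinetic scheme (CSR by source state)
struct Scheme {
  int n_states;
  std::vector<int> ptr, to, dyn, act, na_delta;
  std::vector<double> p;
  std::string name;
};

static Scheme unpack_scheme(List s) {
  Scheme sc;
  sc.n_states = as<int>(s["n_states"]);
  sc.ptr = as<std::vector<int>>(s["ptr"]);
  sc.to = as<std::vector<int>>(s["to"]);
  sc.dyn = as<std::vector<int>>(s["dyn"]);
  sc.act = as<std::vector<int>>(s["act"]);
  sc.na_delta = as<std::vector<int>>(s["na_delta"]);
  sc.p = as<std::vector<double>>(s["p"]);
  sc.name = as<std::string>(s["name"]);
  return sc;
}

// Evolve independent Markov chains with fixed per-step probabilities
// (pre-equilibration: concentrations pinned, no particle bookkeeping).
// [[Rcpp::export]]
IntegerVector evolve_states_cpp(IntegerVector states, List scheme, int n_steps) {
  RNGScope scope;
  Scheme sc = unpack_scheme(scheme);
  // static sanity: total exit probability < 1 everywhere
  for (int s = 0; s < sc.n_states; ++s) {
    double tot = 0.0;
    for (int t = sc.ptr[s]; t < sc.ptr[s + 1]; ++t) tot += sc.p[t];
    if (tot >= 1.0)
      stop("Time-step violation in scheme '%s': exit probability %.3f >= 1 from state %d.",
           sc.name.c_str(), tot, s + 1);
  }
  int n = states.size();
  std::vector<int> st(n);
  for (int i = 0; i < n; ++i) st[i] = states[i] - 1;
  std::vector<double> tot(sc.n_states, 0.0);
  for (int s = 0; s < sc.n_states; ++s)
    for (int t = sc.ptr[s]; t < sc.ptr[s + 1]; ++t) tot[s] += sc.p[t];
  for (int step = 0; step < n_steps; ++step) {
    for (int i = 0; i < n; ++i) {
      double u = unif_rand();
      int s = st[i];
      if (u >= tot[s]) continue;
      double cum = 0.0;
      for (int t = sc.ptr[s]; t < sc.ptr[s + 1]; ++t) {
        cum += sc.p[t];
        if (u < cum) { st[i] = sc.to[t]; break; }
      }
    }
  }
  IntegerVector out(n);
  for (int i = 0; i < n; ++i) out[i] = st[i] + 1;
  return out;
}

struct Pool {
  std::vector<double> x, y, z;
  std::vector<int> st;
  int free_count = 0;
  int baseline = 0;
  void load(NumericMatrix pos, int base) {
    int n = pos.nrow();
    x.resize(n); y.resize(n); z.resize(n); st.assign(n, P_FREE);
    for (int i = 0; i < n; ++i) { x[i] = pos(i,0); y[i] = pos(i,1); z[i] = pos(i,2); }
    free_count = n;
    baseline = base;
  }
  int add(double px, double py, double pz) {
    x.push_back(px); y.push_back(py); z.push_back(pz); st.push_back(P_FREE);
    ++free_count;
    return (int)x.size() - 1;
  }
};

// spatial hash of free glutamate for 50 nm microdomain queries
struct Bins {
  double cell;
  int nbx, nby, nbz;
  std::vector<int> head, nxt;
  void init(double ext_x, double ext_y, double ext_z, double cell_nm) {
    cell = cell_nm;
    nbx = std::max(1, (int)std::ceil(ext_x / cell));
    nby = std::max(1, (int)std::ceil(ext_y / cell));
    nbz = std::max(1, (int)std::ceil(ext_z / cell));
    head.assign((size_t)nbx * nby * nbz, -1);
  }
  inline int cidx(int bi, int bj, int bk) const {
    return bi + nbx * (bj + nby * bk);
  }
  void rebuild(const Pool& p) {
    std::fill(head.begin(), head.end(), -1);
    nxt.assign(p.x.size(), -1);
    for (size_t i = 0; i < p.x.size(); ++i) {
      if (p.st[i] != P_FREE) continue;
      int bi = std::min(nbx - 1, std::max(0, (int)(p.x[i] / cell)));
      int bj = std::min(nby - 1, std::max(0, (int)(p.y[i] / cell)));
      int bk = std::min(nbz - 1, std::max(0, (int)(p.z[i] / cell)));
      int c = cidx(bi, bj, bk);
      nxt[i] = head[c];
      head[c] = (int)i;
    }
  }
  // count free particles in the box [c - h, c + h]^3; if pick >= 0, return
  // the pick-th such particle index in -sel
  int box_count(const Pool& p, double cx, double cy, double cz, double h,
                int pick, int* sel) const {
    int i0 = std::max(0, (int)((cx - h) / cell));
    int i1 = std::min(nbx - 1, (int)((cx + h) / cell));
    int j0 = std::max(0, (int)((cy - h) / cell));
    int j1 = std::min(nby - 1, (int)((cy + h) / cell));
    int k0 = std::max(0, (int)((cz - h) / cell));
    int k1 = std::min(nbz - 1, (int)((cz + h) / cell));
    int count = 0;
    if (sel) *sel = -1;
    for (int bk = k0; bk <= k1; ++bk)
      for (int bj = j0; bj <= j1; ++bj)
        for (int bi = i0; bi <= i1; ++bi) {
          for (int t = head[cidx(bi, bj, bk)]; t >= 0; t = nxt[t]) {
            if (p.st[t] != P_FREE) continue;
            if (std::fabs(p.x[t] - cx) <= h && std::fabs(p.y[t] - cy) <= h &&
                std::fabs(p.z[t] - cz) <= h) {
              if (sel && count == pick) *sel = t;
              ++count;
            }
          }
        }
    return count;
  }
};

// [[Rcpp::export]]
List run_engine_cpp(IntegerVector labels, IntegerVector dim, NumericVector pitch,
                    int ecs_id, int astro_id,
                    Nullable<List> eaat_, Nullable<List> ncx_,
                    NumericMatrix glu_pos, int glu_baseline,
                    NumericMatrix ca_pos, int ca_baseline,
                    double na_mM, double na_per_ion_mM, double ca_per_ion_mM,
                    double sd_glu_nm, double sd_ca_nm,
                    int n_steps, int record_every,
                    int release_step, NumericMatrix release_cand, int release_n,
                    double box_half_nm, double ca_bind_radius_nm) {
  RNGScope scope;
  Grid g{labels.begin(), dim[0], dim[1], dim[2], pitch[0], pitch[1], pitch[2]};
  double ext_x = g.nx * g.dx, ext_y = g.ny * g.dy, ext_z = g.nz * g.dz;

  Pool glu, ca;
  glu.load(glu_pos, glu_baseline);
  ca.load(ca_pos, ca_baseline);

  bool has_eaat = eaat_.isNotNull();
  bool has_ncx = ncx_.isNotNull();

  Scheme sc_e, sc_n;
  std::vector<int> est, nst;                 // current states (0-based)
  std::vector<double> ex, ey, ez;            // EAAT membrane positions
  std::vector<double> erx, ery, erz;         // EAAT ECS-side release points
  std::vector<double> ebox_conv;             // count -> local mM per EAAT
  std::vector<int> ebound;                   // 0 none / 1 real / 2 ghost
  std::vector<int> ebound_idx;
  std::vector<double> nrx, nry, nrz;         // NCX astro-side release points
  std::vector<int> nbound, nbound_idx;
  std::vector<double> ecnt_events, ncnt_events;

  if (has_eaat) {
    List e(eaat_);
    sc_e = unpack_scheme(as<List>(e["scheme"]));
    IntegerVector s0 = e["states"];
    NumericMatrix pos = e["pos"], rel = e["release_pos"];
    NumericVector conv = e["box_conv_mM"];
    int n = s0.size();
    est.resize(n); ex.resize(n); ey.resize(n); ez.resize(n);
    erx.resize(n); ery.resize(n); erz.resize(n);
    ebox_conv.resize(n);
    ebound.assign(n, 0); ebound_idx.assign(n, -1);
    for (int i = 0; i < n; ++i) {
      est[i] = s0[i] - 1;
      ex[i] = pos(i,0); ey[i] = pos(i,1); ez[i] = pos(i,2);
      erx[i] = rel(i,0); ery[i] = rel(i,1); erz[i] = rel(i,2);
      ebox_conv[i] = conv[i];
    }
    ecnt_events.assign(sc_e.to.size(), 0.0);
  }
  if (has_ncx) {
    List e(ncx_);
    sc_n = unpack_scheme(as<List>(e["scheme"]));
    IntegerVector s0 = e["states"];
    NumericMatrix rel = e["release_pos"];
    int n = s0.size();
    nst.resize(n);
    nrx.resize(n); nry.resize(n); nrz.resize(n);
    nbound.assign(n, 0); nbound_idx.assign(n, -1);
    for (int i = 0; i < n; ++i) {
      nst[i] = s0[i] - 1;
      nrx[i] = rel(i,0); nry[i] = rel(i,1); nrz[i] = rel(i,2);
    }
    ncnt_events.assign(sc_n.to.size(), 0.0);
  }

  int nE = (int)est.size(), nN = (int)nst.size();
  std::vector<int> order(nE + nN);
  for (int i = 0; i < nE + nN; ++i) order[i] = i;

  Bins bins;
  if (has_eaat) {
    bins.init(ext_x, ext_y, ext_z, std::max(2.0 * box_half_nm, 25.0));
  }

  // ledger
  double removed_glu = 0, removed_ca = 0, cyto_glu = 0, glu_created_out = 0,
         ca_efflux = 0, ca_influx_created = 0, cancelled_glu = 0,
         cancelled_ca = 0, released_total = 0;

  int n_rec = n_steps / record_every + 1;
  NumericMatrix rec(n_rec, 3);
  rec(0, 0) = glu.free_count; rec(0, 1) = ca.free_count; rec(0, 2) = na_mM;

  double r2_bind = ca_bind_radius_nm * ca_bind_radius_nm;

  for (int s = 0; s < n_steps; ++s) {
    // synaptic release: new free Glu at the nearest-ECS-voxel candidates
    if (s == release_step && release_n > 0) {
      int m = release_cand.nrow();
      for (int r = 0; r < release_n; ++r) {
        int c = std::min(m - 1, (int)(unif_rand() * m));
        double px = release_cand(c,0) + (unif_rand() - 0.5) * g.dx;
        double py = release_cand(c,1) + (unif_rand() - 0.5) * g.dy;
        double pz = release_cand(c,2) + (unif_rand() - 0.5) * g.dz;
        glu.add(px, py, pz);
      }
      released_total += release_n;
    }

    // (1) particle moves
    if (sd_glu_nm > 0 && glu.free_count > 0)
      removed_glu += diffuse_sweep(glu.x, glu.y, glu.z, glu.st, g, ecs_id,
                                   sd_glu_nm, glu.baseline, glu.free_count);
    if (sd_ca_nm > 0 && ca.free_count > 0)
      removed_ca += diffuse_sweep(ca.x, ca.y, ca.z, ca.st, g, astro_id,
                                  sd_ca_nm, ca.baseline, ca.free_count);

    // (2) transporter transitions, shuffled processing order. Dynamic
    // concentrations (Na_i, free Ca_i, local Glu counts) are sampled at the
    // start of the step; per-ion increments are far below any rate's
    // sensitivity at 1 us resolution.
    if (nE + nN > 0) {
      if (has_eaat) bins.rebuild(glu);
      double f_na = na_mM;
      double f_na3 = na_mM * na_mM * na_mM;
      double f_ca = ca.free_count * ca_per_ion_mM;
      // per-step effective probabilities and per-state totals
      std::vector<double> peff_e, peff_n, tot_e, tot_n;
      std::vector<int> d1_e, d1_n; // dyn-local transition per state, or -1
      for (int which = 0; which < 2; ++which) {
        if (which == 0 && !has_eaat) continue;
        if (which == 1 && !has_ncx) continue;
        const Scheme& sc = which == 0 ? sc_e : sc_n;
        std::vector<double>& peff = which == 0 ? peff_e : peff_n;
        std::vector<double>& tot = which == 0 ? tot_e : tot_n;
        std::vector<int>& d1 = which == 0 ? d1_e : d1_n;
        peff.assign(sc.p.size(), 0.0);
        tot.assign(sc.n_states, 0.0);
        d1.assign(sc.n_states, -1);
        for (int ss = 0; ss < sc.n_states; ++ss) {
          for (int t = sc.ptr[ss]; t < sc.ptr[ss + 1]; ++t) {
            double pt = sc.p[t];
            switch (sc.dyn[t]) {
            case D_GLU_LOCAL: d1[ss] = t; pt = 0.0; break;
            case D_NA_I: pt *= f_na; break;
            case D_NA_I3: pt *= f_na3; break;
            case D_CA_I: pt *= f_ca; break;
            }
            peff[t] = pt;
            tot[ss] += pt;
          }
          if (d1[ss] < 0 && tot[ss] >= 1.0)
            stop("Time-step violation in scheme '%s': exit probability %.3f >= 1 from state %d at step %d.",
                 sc.name.c_str(), tot[ss], ss + 1, s + 1);
        }
      }
      for (int i = nE + nN - 1; i > 0; --i) {
        int j = (int)(unif_rand() * (i + 1));
        if (j > i) j = i;
        std::swap(order[i], order[j]);
      }
      for (int oi = 0; oi < nE + nN; ++oi) {
        int id = order[oi];
        bool is_eaat = id < nE;
        const Scheme& sc = is_eaat ? sc_e : sc_n;
        const std::vector<double>& peff = is_eaat ? peff_e : peff_n;
        const std::vector<double>& tot = is_eaat ? tot_e : tot_n;
        int mi = is_eaat ? id : id - nE;
        int st0 = is_eaat ? est[mi] : nst[mi];
        double u = unif_rand();
        double tot_s = tot[st0];
        int dloc = is_eaat ? d1_e[st0] : (has_ncx ? d1_n[st0] : -1);
        double p_loc = 0.0;
        if (dloc >= 0) {
          int cnt = bins.box_count(glu, ex[mi], ey[mi], ez[mi], box_half_nm,
                                   -1, nullptr);
          p_loc = sc.p[dloc] * cnt * ebox_conv[mi];
          tot_s += p_loc;
          if (tot_s >= 1.0)
            stop("Time-step violation in scheme '%s': exit probability %.3f >= 1 from state %d at step %d.",
                 sc.name.c_str(), tot_s, st0 + 1, s + 1);
        }
        if (u >= tot_s) continue;
        double cum = 0.0;
        int chosen = -1;
        for (int t = sc.ptr[st0]; t < sc.ptr[st0 + 1]; ++t) {
          cum += (t == dloc) ? p_loc : peff[t];
          if (u < cum) { chosen = t; break; }
        }
        if (chosen < 0) continue;

        int act = sc.act[chosen];
        bool vetoed = false;
        switch (act) {
        case A_GLU_BIND: {
          int cnt = bins.box_count(glu, ex[mi], ey[mi], ez[mi], box_half_nm,
                                   -1, nullptr);
          if (cnt == 0) { vetoed = true; cancelled_glu += 1; break; }
          int pick = std::min(cnt - 1, (int)(unif_rand() * cnt));
          int sel = -1;
          bins.box_count(glu, ex[mi], ey[mi], ez[mi], box_half_nm, pick, &sel);
          if (sel < 0) { vetoed = true; cancelled_glu += 1; break; }
          glu.st[sel] = P_BOUND;
          --glu.free_count;
          ebound[mi] = 1; ebound_idx[mi] = sel;
          break; }
        case A_GLU_RELEASE_OUT: {
          if (ebound[mi] == 1) {
            int p = ebound_idx[mi];
            glu.st[p] = P_FREE;
            glu.x[p] = erx[mi]; glu.y[p] = ery[mi]; glu.z[p] = erz[mi];
            ++glu.free_count;
          } else if (ebound[mi] == 2) {
            glu.add(erx[mi], ery[mi], erz[mi]);
            glu_created_out += 1;
          }
          ebound[mi] = 0; ebound_idx[mi] = -1;
          break; }
        case A_GLU_RELEASE_IN: {
          if (ebound[mi] == 1) {
            glu.st[ebound_idx[mi]] = P_GONE;
            cyto_glu += 1;
          }
          ebound[mi] = 0; ebound_idx[mi] = -1;
          break; }
        case A_GLU_LOAD_IN:
          ebound[mi] = 2; ebound_idx[mi] = -1;
          break;
        case A_CA_BIND_IN: {
          double cx = nrx[mi], cy = nry[mi], cz = nrz[mi];
          int best = -1; double bestd = r2_bind;
          for (size_t p = 0; p < ca.x.size(); ++p) {
            if (ca.st[p] != P_FREE) continue;
            double ddx = ca.x[p] - cx, ddy = ca.y[p] - cy, ddz = ca.z[p] - cz;
            double d2 = ddx * ddx + ddy * ddy + ddz * ddz;
            if (d2 <= bestd) { bestd = d2; best = (int)p; }
          }
          if (best < 0) { vetoed = true; cancelled_ca += 1; break; }
          ca.st[best] = P_BOUND;
          --ca.free_count;
          nbound[mi] = 1; nbound_idx[mi] = best;
          break; }
        case A_CA_RELEASE_IN: {
          if (nbound[mi] == 1) {
            int p = nbound_idx[mi];
            ca.st[p] = P_FREE;
            ca.x[p] = nrx[mi]; ca.y[p] = nry[mi]; ca.z[p] = nrz[mi];
            ++ca.free_count;
          } else if (nbound[mi] == 2) {
            ca.add(nrx[mi], nry[mi], nrz[mi]);
            ca_influx_created += 1;
          }
          nbound[mi] = 0; nbound_idx[mi] = -1;
          break; }
        case A_CA_RELEASE_OUT: {
          if (nbound[mi] == 1) {
            ca.st[nbound_idx[mi]] = P_GONE;
            ca_efflux += 1;
          }
          nbound[mi] = 0; nbound_idx[mi] = -1;
          break; }
        case A_CA_LOAD_OUT:
          nbound[mi] = 2; nbound_idx[mi] = -1;
          break;
        }

        if (!vetoed) {
          // (3) bookkeeping: sodium stoichiometry, state update, event tally
          if (sc.na_delta[chosen] != 0) {
            na_mM += sc.na_delta[chosen] * na_per_ion_mM;
            if (na_mM < 0) na_mM = 0;
          }
          if (is_eaat) { est[mi] = sc.to[chosen]; ecnt_events[chosen] += 1; }
          else { nst[mi] = sc.to[chosen]; ncnt_events[chosen] += 1; }
        }
      }
    }

    if ((s + 1) % record_every == 0) {
      int r = (s + 1) / record_every;
      rec(r, 0) = glu.free_count;
      rec(r, 1) = ca.free_count;
      rec(r, 2) = na_mM;
    }
  }

  int glu_bound = 0, ca_bound = 0;
  for (int v : glu.st) if (v == P_BOUND) ++glu_bound;
  for (int v : ca.st) if (v == P_BOUND) ++ca_bound;

  List out = List::create(
    _["records"] = rec,
    _["ledger"] = NumericVector::create(
      _["glu_free"] = glu.free_count, _["glu_bound"] = glu_bound,
      _["glu_translocated_in"] = cyto_glu,
      _["glu_boundary_removed"] = removed_glu,
      _["glu_created_out"] = glu_created_out,
      _["glu_released"] = released_total,
      _["glu_baseline"] = glu.baseline,
      _["glu_cancelled_bind"] = cancelled_glu,
      _["ca_free"] = ca.free_count, _["ca_bound"] = ca_bound,
      _["ca_translocated_out"] = ca_efflux,
      _["ca_boundary_removed"] = removed_ca,
      _["ca_influx_created"] = ca_influx_created,
      _["ca_baseline"] = ca.baseline,
      _["ca_cancelled_bind"] = cancelled_ca),
    _["na_mM"] = na_mM);
  if (has_eaat) {
    IntegerVector fs(nE);
    for (int i = 0; i < nE; ++i) fs[i] = est[i] + 1;
    out["eaat_states"] = fs;
    out["eaat_events"] = NumericVector(ecnt_events.begin(), ecnt_events.end());
  }
  if (has_ncx) {
    IntegerVector fs(nN);
    for (int i = 0; i < nN; ++i) fs[i] = nst[i] + 1;
    out["ncx_states"] = fs;
    out["ncx_events"] = NumericVector(ncnt_events.begin(), ncnt_events.end());
  }
  return out;
}
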