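// Monte Carlo photon transport under the kerma approximation.
//
// Physics: photoelectric absorption, coherent (Thomson-shaped) scattering and
// incoherent (Klein-Nishina / Kahn-sampled) scattering; electrons are not
// transported -- the energy transferred to them is deposited at the
// interaction site.  Photons below the low-energy cutoff deposit locally.
//
// Geometry: voxel grids traversed with an incremental Amanatides-Woo /
// Siddon-style walk; free paths sampled by accumulating optical depth
// -log(xi) across voxels.
//
// Scoring: mode 0 (collision) deposits analog energy into tally boxes with an
// exact per-history energy ledger; mode 1 (kerma) adds a next-event
// (point-detector) estimate of the scatter kerma at each point of interest at
// every scattering event (the deterministic primary component is added on the
// R side); mode 2 (primary-only) terminates histories at their first
// interaction; mode 3 (tracklength) scores kerma from chord lengths through
// the tally boxes (flux x muen/rho x E); mode 4 is track-length scoring with
// primary-only transport.

#include <Rcpp.h>
#include <cmath>
#include <cstdint>
#include <vector>
using namespace Rcpp;

// ---------------------------------------------------------------- RNG -----
// xoshiro256++, seeded via splitmix64: a small, named, counter-seeded
// generator giving bit-reproducible streams independent of R's RNG.
struct Xoshiro {
  uint64_t s[4];
  explicit Xoshiro(uint64_t seed) {
    uint64_t x = seed;
    for (int i = 0; i < 4; i++) {
      x += 0x9e3779b97f4a7c15ULL;
      uint64_t z = x;
      z = (z ^ (z >> 30)) * 0xbf58476d1ce4e5b9ULL;
      z = (z ^ (z >> 27)) * 0x94d049bb133111ebULL;
      s[i] = z ^ (z >> 31);
    }
  }
  static inline uint64_t rotl(uint64_t x, int k) {
    return (x << k) | (x >> (64 - k));
  }
  inline uint64_t next() {
    uint64_t result = rotl(s[0] + s[3], 23) + s[0];
    uint64_t t = s[1] << 17;
    s[2] ^= s[0]; s[3] ^= s[1]; s[1] ^= s[2]; s[0] ^= s[3];
    s[2] ^= t; s[3] = rotl(s[3], 45);
    return result;
  }
  inline double unif() {  // in (0, 1)
    return ((next() >> 11) + 0.5) * (1.0 / 9007199254740992.0);
  }
};

// ---------------------------------------------------------- materials -----
struct MatTable {
  std::vector<double> loge, logmu, logmuen, fph, fco, fin;
  double emin, emax;

  inline int bracket(double le) const {
    int lo = 0, hi = (int)loge.size() - 1;
    while (hi - lo > 1) {
      int mid = (lo + hi) / 2;
      if (loge[mid] <= le) lo = mid; else hi = mid;
    }
    return lo;
  }
  inline double mu_rho(double e) const {
    double le = std::log(std::min(std::max(e, emin), emax));
    int i = bracket(le);
    double t = (le - loge[i]) / (loge[i + 1] - loge[i]);
    return std::exp(logmu[i] + t * (logmu[i + 1] - logmu[i]));
  }
  inline double muen_rho(double e) const {
    double le = std::log(std::min(std::max(e, emin), emax));
    int i = bracket(le);
    double t = (le - loge[i]) / (loge[i + 1] - loge[i]);
    return std::exp(logmuen[i] + t * (logmuen[i + 1] - logmuen[i]));
  }
  inline void fractions(double e, double &ph, double &co, double &in) const {
    double le = std::log(std::min(std::max(e, emin), emax));
    int i = bracket(le);
    double t = (le - loge[i]) / (loge[i + 1] - loge[i]);
    ph = fph[i] + t * (fph[i + 1] - fph[i]);
    co = fco[i] + t * (fco[i + 1] - fco[i]);
    in = fin[i] + t * (fin[i + 1] - fin[i]);
    double s = ph + co + in;
    ph /= s; co /= s; in /= s;
  }
};

static std::vector<MatTable> parse_materials(List mats) {
  std::vector<MatTable> out(mats.size());
  for (int m = 0; m < mats.size(); m++) {
    List mm = mats[m];
    NumericVector e = mm["e"], mu = mm["mu"], muen = mm["muen"],
                  fph = mm["fphoto"], fco = mm["fcoh"], fin = mm["finc"];
    MatTable &t = out[m];
    t.emin = e[0]; t.emax = e[e.size() - 1];
    for (int i = 0; i < e.size(); i++) {
      t.loge.push_back(std::log(e[i]));
      t.logmu.push_back(std::log(mu[i]));
      t.logmuen.push_back(std::log(muen[i]));
      t.fph.push_back(fph[i]); t.fco.push_back(fco[i]);
      t.fin.push_back(fin[i]);
    }
  }
  return out;
}

// ------------------------------------------------------------ phantom -----
struct Grid {
  int nx, ny, nz;
  double dx, dy, dz, ox, oy, oz;
  const int *mat;       // 0-based material index per voxel, x-fastest
  const double *rho;

  inline int idx(int i, int j, int k) const { return i + nx * (j + ny * k); }
  inline bool inside(int i, int j, int k) const {
    return i >= 0 && i < nx && j >= 0 && j < ny && k >= 0 && k < nz;
  }
  // entry distance of ray p + t*d into the box, or -1 if it misses
  double entry(const double *p, const double *d) const {
    double t0 = 0.0, t1 = 1e300;
    const double lo[3] = {ox, oy, oz};
    const double hi[3] = {ox + nx * dx, oy + ny * dy, oz + nz * dz};
    for (int a = 0; a < 3; a++) {
      if (std::fabs(d[a]) < 1e-300) {
        if (p[a] <= lo[a] || p[a] >= hi[a]) return -1.0;
      } else {
        double ta = (lo[a] - p[a]) / d[a], tb = (hi[a] - p[a]) / d[a];
        if (ta > tb) std::swap(ta, tb);
        if (ta > t0) t0 = ta;
        if (tb < t1) t1 = tb;
      }
    }
    return (t0 <= t1) ? t0 : -1.0;
  }
};

static Grid parse_grid(List ph, IntegerVector &matstore,
                       NumericVector &rhostore) {
  Grid g;
  IntegerVector dims = ph["dims"];
  NumericVector sp = ph["spacing"], org = ph["origin"];
  matstore = ph["material"];   // already 0-based
  rhostore = ph["density"];
  g.nx = dims[0]; g.ny = dims[1]; g.nz = dims[2];
  g.dx = sp[0]; g.dy = sp[1]; g.dz = sp[2];
  g.ox = org[0]; g.oy = org[1]; g.oz = org[2];
  g.mat = INTEGER(matstore);
  g.rho = REAL(rhostore);
  return g;
}

// Incremental voxel walk.  Visits segments (voxel, length) along p + t*d,
// calling F(voxel_index, seglen) -> bool (false stops the walk), for at most
// tmax total in-box path length (tmax < 0 means until exit).
template <typename F>
static void walk(const Grid &g, const double *p0, const double *d,
                 double tmax, F f) {
  double p[3] = {p0[0], p0[1], p0[2]};
  double t = g.entry(p0, d);
  if (t < 0) return;
  t += 1e-9;  // nudge inside
  p[0] = p0[0] + t * d[0]; p[1] = p0[1] + t * d[1]; p[2] = p0[2] + t * d[2];
  int i = (int)std::floor((p[0] - g.ox) / g.dx);
  int j = (int)std::floor((p[1] - g.oy) / g.dy);
  int k = (int)std::floor((p[2] - g.oz) / g.dz);
  if (!g.inside(i, j, k)) return;
  int si = d[0] > 0 ? 1 : -1, sj = d[1] > 0 ? 1 : -1, sk = d[2] > 0 ? 1 : -1;
  double tdx = std::fabs(d[0]) > 1e-300 ? g.dx / std::fabs(d[0]) : 1e300;
  double tdy = std::fabs(d[1]) > 1e-300 ? g.dy / std::fabs(d[1]) : 1e300;
  double tdz = std::fabs(d[2]) > 1e-300 ? g.dz / std::fabs(d[2]) : 1e300;
  double bx = g.ox + (i + (si > 0 ? 1 : 0)) * g.dx;
  double by = g.oy + (j + (sj > 0 ? 1 : 0)) * g.dy;
  double bz = g.oz + (k + (sk > 0 ? 1 : 0)) * g.dz;
  double tmx = std::fabs(d[0]) > 1e-300 ? (bx - p0[0]) / d[0] : 1e300;
  double tmy = std::fabs(d[1]) > 1e-300 ? (by - p0[1]) / d[1] : 1e300;
  double tmz = std::fabs(d[2]) > 1e-300 ? (bz - p0[2]) / d[2] : 1e300;
  double tcur = t;
  double travelled = 0.0;
  while (true) {
    double tnext = std::min(tmx, std::min(tmy, tmz));
    double seg = tnext - tcur;
    if (seg < 0) seg = 0;
    bool last = false;
    if (tmax >= 0 && travelled + seg >= tmax) {
      seg = tmax - travelled;
      last = true;
    }
    if (!f(g.idx(i, j, k), seg)) return;
    travelled += seg;
    if (last) return;
    tcur = tnext;
    if (tmx <= tmy && tmx <= tmz) { i += si; tmx += tdx; }
    else if (tmy <= tmz)          { j += sj; tmy += tdy; }
    else                          { k += sk; tmz += tdz; }
    if (!g.inside(i, j, k)) return;
  }
}

// optical depth along p -> p + L*d at energy e (murho cached per material)
static double optical_depth(const Grid &g, const std::vector<double> &murho,
                            const double *p, const double *d, double L) {
  double tau = 0.0;
  walk(g, p, d, L, [&](int vox, double len) {
    tau += murho[g.mat[vox]] * g.rho[vox] * len;
    return true;
  });
  return tau;
}

// ---------------------------------------------------------- kinematics ----
static const double MEC2 = 510.99895;  // keV

// Kahn's rejection method for the Klein-Nishina energy/angle distribution.
static void kahn_sample(Xoshiro &rng, double e, double &eout, double &ct) {
  double a = e / MEC2;
  double x;  // e / e'
  for (;;) {
    double r1 = rng.unif(), r2 = rng.unif(), r3 = rng.unif();
    if (r1 <= (1.0 + 2.0 * a) / (9.0 + 2.0 * a)) {
      x = 1.0 + 2.0 * a * r2;
      if (r3 <= 4.0 * (1.0 / x - 1.0 / (x * x))) break;
    } else {
      x = (1.0 + 2.0 * a) / (1.0 + 2.0 * a * r2);
      double c = 1.0 - (x - 1.0) / a;
      if (r3 <= 0.5 * (c * c + 1.0 / x)) break;
    }
  }
  ct = 1.0 - (x - 1.0) / a;
  eout = e / x;
}

// Thomson-shaped coherent angle: pdf proportional to 1 + cos^2
static double thomson_sample(Xoshiro &rng) {
  for (;;) {
    double c = 2.0 * rng.unif() - 1.0;
    if (rng.unif() <= 0.5 * (1.0 + c * c)) return c;
  }
}

// total Klein-Nishina cross section per electron (relative units; the
// classical-electron-radius factor cancels against the differential form)
static double kn_total_rel(double e) {
  double k = e / MEC2;
  double t1 = (1 + k) / (k * k) *
              (2 * (1 + k) / (1 + 2 * k) - std::log(1 + 2 * k) / k);
  double t2 = std::log(1 + 2 * k) / (2 * k);
  double t3 = -(1 + 3 * k) / ((1 + 2 * k) * (1 + 2 * k));
  return 2.0 * M_PI * (t1 + t2 + t3);
}

// Klein-Nishina differential (same relative units) at scatter cosine ct
static double kn_diff_rel(double e, double ct) {
  double k = e / MEC2;
  double ep = e / (1.0 + k * (1.0 - ct));
  double r = ep / e;
  return 0.5 * r * r * (1.0 / r + r - (1.0 - ct * ct));
}

static void rotate(const double *u, double ct, double phi, double *w) {
  double st = std::sqrt(std::max(0.0, 1.0 - ct * ct));
  double cp = std::cos(phi), sp = std::sin(phi);
  double s = std::sqrt(u[0] * u[0] + u[1] * u[1]);
  if (s < 1e-12) {
    double sgn = u[2] >= 0 ? 1.0 : -1.0;
    w[0] = st * cp; w[1] = st * sp; w[2] = sgn * ct;
  } else {
    w[0] = u[0] * ct + st * (u[0] * u[2] * cp - u[1] * sp) / s;
    w[1] = u[1] * ct + st * (u[1] * u[2] * cp + u[0] * sp) / s;
    w[2] = u[2] * ct - st * cp * s;
  }
  double n = std::sqrt(w[0] * w[0] + w[1] * w[1] + w[2] * w[2]);
  w[0] /= n; w[1] /= n; w[2] /= n;
}

// ------------------------------------------------------------- driver -----
// [[Rcpp::export]]
List mc_run(List phantom, List materials, NumericMatrix emissions,
            NumericMatrix tallies, NumericVector tally_half,
            int mode, double cutoff, double seed, bool coherent_on,
            double nee_rmin) {
  IntegerVector matstore; NumericVector rhostore;
  Grid g = parse_grid(phantom, matstore, rhostore);
  std::vector<MatTable> mt = parse_materials(materials);
  int nmat = (int)mt.size();
  int nt = tallies.nrow();
  int nh = emissions.nrow();
  Xoshiro rng((uint64_t)seed);

  std::vector<double> acc1(nt, 0.0), acc2(nt, 0.0), hsum(nt, 0.0);
  double launched = 0.0, deposited = 0.0, escaped = 0.0;
  double max_imbalance = 0.0;
  long long ncol = 0;
  std::vector<double> murho(nmat), murho_nee(nmat);

  // tally-voxel material/density at each POI (for the kerma weighting and
  // the collision-mode tally mass)
  std::vector<int> poi_mat(nt, 0);
  for (int q = 0; q < nt; q++) {
    int i = (int)std::floor((tallies(q, 0) - g.ox) / g.dx);
    int j = (int)std::floor((tallies(q, 1) - g.oy) / g.dy);
    int k = (int)std::floor((tallies(q, 2) - g.oz) / g.dz);
    if (!g.inside(i, j, k)) stop("tally %d outside the phantom", q + 1);
    poi_mat[q] = g.mat[g.idx(i, j, k)];
  }

  for (int h = 0; h < nh; h++) {
    double p[3] = {0.0, 0.0, 0.0};
    double d[3] = {emissions(h, 0), emissions(h, 1), emissions(h, 2)};
    double e = emissions(h, 3);
    double w = emissions(h, 4);
    double dep_h = 0.0, esc_h = 0.0;
    double e0w = w * e;
    launched += e0w;
    std::fill(hsum.begin(), hsum.end(), 0.0);

    bool alive = true;
    int bounces = 0;
    while (alive && bounces < 10000) {
      bounces++;
      for (int m = 0; m < nmat; m++) murho[m] = mt[m].mu_rho(e);
      double tau_target = -std::log(rng.unif());
      double tau = 0.0;
      double travelled = -1.0;  // interaction distance; <0 means escaped
      double entry_t = g.entry(p, d);
      if (entry_t >= 0) {
        double tcum = entry_t + 1e-9;
        walk(g, p, d, -1.0, [&](int vox, double len) {
          double mu = murho[g.mat[vox]] * g.rho[vox];
          if (tau + mu * len >= tau_target) {
            double s = (mu > 0) ? (tau_target - tau) / mu : len;
            travelled = tcum + s;
            return false;
          }
          tau += mu * len;
          tcum += len;
          return true;
        });
      }
      if (mode == 3 || mode == 4) {
        // chord of this flight through each tally box -> fluence estimate
        double flen = travelled >= 0 ? travelled : 1e300;
        for (int q = 0; q < nt; q++) {
          double t0 = 0.0, t1 = flen;
          bool missq = false;
          for (int aax = 0; aax < 3; aax++) {
            double lo = tallies(q, aax) - tally_half[aax];
            double hi = tallies(q, aax) + tally_half[aax];
            if (std::fabs(d[aax]) < 1e-300) {
              if (p[aax] <= lo || p[aax] >= hi) { missq = true; break; }
            } else {
              double ta = (lo - p[aax]) / d[aax], tb = (hi - p[aax]) / d[aax];
              if (ta > tb) std::swap(ta, tb);
              if (ta > t0) t0 = ta;
              if (tb < t1) t1 = tb;
            }
          }
          if (!missq && t1 > t0) {
            double vol = 8.0 * tally_half[0] * tally_half[1] * tally_half[2];
            hsum[q] += w * (t1 - t0) / vol * mt[poi_mat[q]].muen_rho(e) * e;
          }
        }
      }
      if (travelled < 0) {  // left the phantom (or missed it)
        esc_h += w * e;
        break;
      }
      p[0] += travelled * d[0]; p[1] += travelled * d[1];
      p[2] += travelled * d[2];
      int vi = (int)std::floor((p[0] - g.ox) / g.dx);
      int vj = (int)std::floor((p[1] - g.oy) / g.dy);
      int vk = (int)std::floor((p[2] - g.oz) / g.dz);
      if (!g.inside(vi, vj, vk)) { esc_h += w * e; break; }
      int lmat = g.mat[g.idx(vi, vj, vk)];
      ncol++;

      auto deposit = [&](double amount) {
        dep_h += amount;
        if (mode == 0 || mode == 2) {
          for (int q = 0; q < nt; q++) {
            if (std::fabs(p[0] - tallies(q, 0)) <= tally_half[0] &&
                std::fabs(p[1] - tallies(q, 1)) <= tally_half[1] &&
                std::fabs(p[2] - tallies(q, 2)) <= tally_half[2]) {
              hsum[q] += amount;
            }
          }
        }
      };

      if (mode == 2 || mode == 4) {  // primary-only: absorb at first interaction
        deposit(w * e);
        break;
      }

      double fph, fco, fin;
      mt[lmat].fractions(e, fph, fco, fin);
      if (!coherent_on) { fco = 0.0; double s = fph + fin; fph /= s; fin /= s; }
      double u = rng.unif();
      int kind = (u < fph) ? 0 : (u < fph + fco ? 1 : 2);

      if (kind == 0) {  // photoelectric: full local absorption
        deposit(w * e);
        break;
      }

      // scattering: next-event point-detector contribution of the emerging
      // photon, then analog continuation
      if (mode == 1 && nt > 0) {
        double kn_norm = kn_total_rel(e);
        for (int q = 0; q < nt; q++) {
          double rv[3] = {tallies(q, 0) - p[0], tallies(q, 1) - p[1],
                          tallies(q, 2) - p[2]};
          double r = std::sqrt(rv[0] * rv[0] + rv[1] * rv[1] + rv[2] * rv[2]);
          if (r < 1e-9) continue;
          double dir_q[3] = {rv[0] / r, rv[1] / r, rv[2] / r};
          double ct = d[0] * dir_q[0] + d[1] * dir_q[1] + d[2] * dir_q[2];
          double eq, pdf;
          if (kind == 1) {
            eq = e;
            pdf = 3.0 / (16.0 * M_PI) * (1.0 + ct * ct);
          } else {
            eq = e / (1.0 + e / MEC2 * (1.0 - ct));
            pdf = kn_diff_rel(e, ct) / kn_norm;
          }
          if (eq <= cutoff) continue;  // would be absorbed on the spot
          for (int m = 0; m < nmat; m++) murho_nee[m] = mt[m].mu_rho(eq);
          double geom;
          if (r < nee_rmin) {
            double mu_loc = murho_nee[lmat] * g.rho[g.idx(vi, vj, vk)];
            geom = 3.0 * (1.0 - std::exp(-mu_loc * nee_rmin)) /
                   (mu_loc * nee_rmin * nee_rmin * nee_rmin);
          } else {
            double tau_q = optical_depth(g, murho_nee, p, dir_q, r);
            geom = std::exp(-tau_q) / (r * r);
          }
          hsum[q] += w * pdf * geom * mt[poi_mat[q]].muen_rho(eq) * eq;
        }
      }

      double ct, enew, phi = 2.0 * M_PI * rng.unif();
      if (kind == 1) {
        ct = thomson_sample(rng);
        enew = e;
      } else {
        kahn_sample(rng, e, enew, ct);
        deposit(w * (e - enew));
      }
      double wdir[3];
      rotate(d, ct, phi, wdir);
      d[0] = wdir[0]; d[1] = wdir[1]; d[2] = wdir[2];
      e = enew;
      if (e <= cutoff) {  // local absorption below cutoff
        deposit(w * e);
        break;
      }
    }

    deposited += dep_h;
    escaped += esc_h;
    double imb = std::fabs(e0w - dep_h - esc_h);
    if (imb > max_imbalance) max_imbalance = imb;
    for (int q = 0; q < nt; q++) {
      acc1[q] += hsum[q];
      acc2[q] += hsum[q] * hsum[q];
    }
  }

  return List::create(
      _["acc1"] = NumericVector(acc1.begin(), acc1.end()),
      _["acc2"] = NumericVector(acc2.begin(), acc2.end()),
      _["launched"] = launched, _["deposited"] = deposited,
      _["escaped"] = escaped, _["max_imbalance"] = max_imbalance,
      _["n_collisions"] = (double)ncol);
}

// Sampled free-path lengths from a fixed state (for distribution tests);
// +Inf marks escape through the phantom boundary.
// [[Rcpp::export]]
NumericVector mc_free_paths(List phantom, List materials, NumericVector pos,
                            NumericVector dir, double energy, int n,
                            double seed) {
  IntegerVector matstore; NumericVector rhostore;
  Grid g = parse_grid(phantom, matstore, rhostore);
  std::vector<MatTable> mt = parse_materials(materials);
  std::vector<double> murho(mt.size());
  for (size_t m = 0; m < mt.size(); m++) murho[m] = mt[m].mu_rho(energy);
  Xoshiro rng((uint64_t)seed);
  NumericVector out(n);
  double p[3] = {pos[0], pos[1], pos[2]};
  double d[3] = {dir[0], dir[1], dir[2]};
  for (int i = 0; i < n; i++) {
    double tau_target = -std::log(rng.unif());
    double tau = 0.0, travelled = -1.0, tcum = 0.0;
    double entry_t = g.entry(p, d);
    if (entry_t >= 0) {
      tcum = entry_t + 1e-9;
      walk(g, p, d, -1.0, [&](int vox, double len) {
        double mu = murho[g.mat[vox]] * g.rho[vox];
        if (tau + mu * len >= tau_target) {
          travelled = tcum + (mu > 0 ? (tau_target - tau) / mu : len);
          return false;
        }
        tau += mu * len; tcum += len;
        return true;
      });
    }
    out[i] = travelled < 0 ? R_PosInf : travelled;
  }
  return out;
}

// Per-voxel chord lengths along the segment p0 -> p1 (clipped to the grid).
// [[Rcpp::export]]
List mc_ray_chords(List phantom, NumericVector p0, NumericVector p1) {
  IntegerVector matstore; NumericVector rhostore;
  Grid g = parse_grid(phantom, matstore, rhostore);
  double d[3] = {p1[0] - p0[0], p1[1] - p0[1], p1[2] - p0[2]};
  double L = std::sqrt(d[0] * d[0] + d[1] * d[1] + d[2] * d[2]);
  for (int a = 0; a < 3; a++) d[a] /= L;
  double p[3] = {p0[0], p0[1], p0[2]};
  double entry_t = g.entry(p, d);
  std::vector<double> lens, rhos;
  std::vector<int> mats;
  if (entry_t >= 0) {
    double remaining = L - std::max(0.0, entry_t);
    if (remaining > 0) {
      walk(g, p, d, remaining, [&](int vox, double len) {
        lens.push_back(len);
        mats.push_back(g.mat[vox] + 1);
        rhos.push_back(g.rho[vox]);
        return true;
      });
    }
  }
  return List::create(_["length_cm"] = NumericVector(lens.begin(), lens.end()),
                      _["material"] = IntegerVector(mats.begin(), mats.end()),
                      _["density"] = NumericVector(rhos.begin(), rhos.end()));
}

// Draw interaction outcomes at a fixed energy in a fixed material (for
// distribution tests): kind 0 = photoelectric, 1 = coherent, 2 = incoherent.
// [[Rcpp::export]]
List mc_sample_interaction(int n, double energy, List material, double seed,
                           bool coherent_on) {
  List one = List::create(material);
  std::vector<MatTable> mt = parse_materials(one);
  double fph, fco, fin;
  mt[0].fractions(energy, fph, fco, fin);
  if (!coherent_on) { fco = 0; double s = fph + fin; fph /= s; fin /= s; }
  Xoshiro rng((uint64_t)seed);
  IntegerVector kind(n);
  NumericVector eout(n), ct(n);
  for (int i = 0; i < n; i++) {
    double u = rng.unif();
    if (u < fph) {
      kind[i] = 0; eout[i] = 0.0; ct[i] = NA_REAL;
    } else if (u < fph + fco) {
      kind[i] = 1; eout[i] = energy; ct[i] = thomson_sample(rng);
    } else {
      kind[i] = 2;
      double e2, c2;
      kahn_sample(rng, energy, e2, c2);
      eout[i] = e2; ct[i] = c2;
    }
  }
  return List::create(_["kind"] = kind, _["energy_out"] = eout,
                      _["cos_theta"] = ct);
}
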