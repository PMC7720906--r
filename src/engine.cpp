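// Monte Carlo photon-transport engine.
//
// Per-photon event loop (hop-drop-spin, matching the reference R engine in
// R/transport.R draw for draw):
//   in material:  xi6 Raman check at the current collision site ->
//                 xi1 free path -> trace segment along the current direction
//                 (truncate at the first interface) -> xi4 absorption
//                 roulette over the traveled length -> [absorbed: xi5
//                 fluorescence branch, two isotropic-direction draws |
//                 at interface: xi7 Fresnel | completed step: xi2 azimuth +
//                 xi3 HG polar deflection at the new collision site]
//   in void:      straight line to the next interface (xi7 Fresnel) or escape.
//
// All uniforms come from one per-batch xoshiro256++ stream (seeded from the
// run seed and the batch index) and can be recorded or replayed so that the
// scalar R reference implementation can reproduce records exactly.

#include <Rcpp.h>
#include <cstdint>
#include <cmath>
#include <vector>
#include <algorithm>
using namespace Rcpp;

static const double EPS_HIT  = 1e-9;  // mm; interface-search exclusion zone
static const double EPS_PUSH = 1e-7;  // mm; nudge off a boundary after an event
static const double TWOPI = 6.283185307179586476925286766559;

// cos/sin evaluated so that the compiler cannot fuse the pair into libm's
// sincos(), whose last-ulp rounding can differ from separate cos()/sin();
// the scalar R reference engine must reproduce the compiled engine's
// records bit-for-bit, and R evaluates the two calls separately.
static inline void cos_sin(double phi, double& c, double& s) {
  c = std::cos(phi);
  volatile double p = phi;  // opaque copy defeats sincos contraction
  s = std::sin(p);
}

// ---------------------------------------------------------------- RNG ----
struct Xoshiro256pp {
  uint64_t s[4];
  static uint64_t splitmix64(uint64_t& x) {
    x += 0x9E3779B97f4A7C15ULL;
    uint64_t z = x;
    z = (z ^ (z >> 30)) * 0xBF58476D1CE4E5B9ULL;
    z = (z ^ (z >> 27)) * 0x94D049BB133111EBULL;
    return z ^ (z >> 31);
  }
  void seed(uint64_t sd) {
    uint64_t x = sd;
    for (int i = 0; i < 4; ++i) s[i] = splitmix64(x);
  }
  static inline uint64_t rotl(uint64_t x, int k) {
    return (x << k) | (x >> (64 - k));
  }
  inline uint64_t next64() {
    const uint64_t result = rotl(s[0] + s[3], 23) + s[0];
    const uint64_t t = s[1] << 17;
    s[2] ^= s[0]; s[3] ^= s[1]; s[1] ^= s[2]; s[0] ^= s[3];
    s[2] ^= t; s[3] = rotl(s[3], 45);
    return result;
  }
  inline double unif() {  // [0, 1)
    return (next64() >> 11) * 0x1.0p-53;
  }
};

struct Stream {
  Xoshiro256pp rng;
  bool replay = false;
  const double* rep = nullptr;
  R_xlen_t rep_n = 0, rep_i = 0;
  std::vector<double>* rec = nullptr;
  inline double next() {
    double u;
    if (replay) {
      if (rep_i >= rep_n) stop("replay variate stream exhausted");
      u = rep[rep_i++];
    } else {
      u = rng.unif();
    }
    if (rec) rec->push_back(u);
    return u;
  }
};

// ----------------------------------------------------------- geometry ----
struct Hit {
  double distance;
  double normal[3];
  int before, after;
};

struct Geom {
  int kind;  // 0 = LAYERED, 1 = VOXEL
  // layered
  std::vector<double> zb;
  std::vector<int> ids;
  double hx, hy;
  // voxel
  const int* labels = nullptr;
  int nx = 0, ny = 0, nz = 0;
  double pitch = 0, ox = 0, oy = 0, oz = 0;
  double reach = 0;

  inline int material_at(double x, double y, double z) const {
    if (kind == 0) {
      if (std::fabs(x) > hx || std::fabs(y) > hy) return 0;
      const int L = (int)ids.size();
      if (z < zb[0] || z >= zb[L]) return 0;
      for (int i = 0; i < L; ++i)
        if (z >= zb[i] && z < zb[i + 1]) return ids[i];
      return 0;
    }
    double i = std::floor((x - ox) / pitch);
    double j = std::floor((y - oy) / pitch);
    double k = std::floor((z - oz) / pitch);
    if (i < 0 || j < 0 || k < 0 || i >= nx || j >= ny || k >= nz) return 0;
    return labels[(R_xlen_t)i + nx * ((R_xlen_t)j + (R_xlen_t)ny * (R_xlen_t)k)];
  }

  bool first_interface(const double* p, const double* u, double step,
                       Hit& h) const {
    const int m0 = material_at(p[0], p[1], p[2]);
    if (kind == 0) return fi_layered(p, u, step, m0, h);
    return fi_voxel(p, u, step, m0, h);
  }

  bool fi_layered(const double* p, const double* u, double step, int m0,
                  Hit& h) const {
    // fast reject: inside the slab and farther than `step` from every face
    if (m0 != 0) {
      const double L = (int)ids.size();
      double margin = hx - std::fabs(p[0]);
      const double my = hy - std::fabs(p[1]);
      if (my < margin) margin = my;
      const double mz1 = p[2] - zb[0], mz2 = zb[(size_t)L] - p[2];
      if (mz1 < margin) margin = mz1;
      if (mz2 < margin) margin = mz2;
      if (step < margin && ids.size() == 1) return false;
    }
    struct Cand { double t; int axis; double sgn; };
    Cand cbuf[64];
    std::vector<Cand> cdyn;
    const size_t ncand_max = zb.size() + 4;
    const bool big = ncand_max > 64;
    if (big) cdyn.reserve(ncand_max);
    size_t nc = 0;
    auto push = [&](double t, int axis, double sgn) {
      if (big) cdyn.push_back({t, axis, sgn});
      else cbuf[nc] = {t, axis, sgn};
      ++nc;
    };
    for (size_t i = 0; i < zb.size(); ++i)
      if (u[2] != 0) {
        double t = (zb[i] - p[2]) / u[2];
        if (t > EPS_HIT && t <= step) push(t, 2, u[2] > 0 ? 1.0 : -1.0);
      }
    for (double xb : {-hx, hx})
      if (u[0] != 0) {
        double t = (xb - p[0]) / u[0];
        if (t > EPS_HIT && t <= step) push(t, 0, u[0] > 0 ? 1.0 : -1.0);
      }
    for (double yb : {-hy, hy})
      if (u[1] != 0) {
        double t = (yb - p[1]) / u[1];
        if (t > EPS_HIT && t <= step) push(t, 1, u[1] > 0 ? 1.0 : -1.0);
      }
    if (nc == 0) return false;
    Cand* cs = big ? cdyn.data() : cbuf;
    // stable insertion sort by t (candidate counts are tiny)
    for (size_t i = 1; i < nc; ++i) {
      Cand key = cs[i];
      size_t j = i;
      while (j > 0 && cs[j - 1].t > key.t) { cs[j] = cs[j - 1]; --j; }
      cs[j] = key;
    }
    for (size_t i = 0; i < nc; ++i) {
      const Cand& c = cs[i];
      const double q[3] = {p[0] + (c.t + EPS_HIT) * u[0],
                           p[1] + (c.t + EPS_HIT) * u[1],
                           p[2] + (c.t + EPS_HIT) * u[2]};
      const int m1 = material_at(q[0], q[1], q[2]);
      if (m1 != m0) {
        h.distance = c.t;
        h.normal[0] = h.normal[1] = h.normal[2] = 0.0;
        h.normal[c.axis] = -c.sgn;
        h.before = m0; h.after = m1;
        return true;
      }
    }
    return false;
  }

  bool fi_voxel(const double* p, const double* u, double step, int m0,
                Hit& h) const {
    const double lo[3] = {ox, oy, oz};
    const double hi[3] = {ox + nx * pitch, oy + ny * pitch, oz + nz * pitch};
    const int dims[3] = {nx, ny, nz};
    double ten = R_NegInf, tex = R_PosInf;
    int enter_axis = 0;
    for (int a = 0; a < 3; ++a) {
      if (u[a] == 0) {
        if (p[a] < lo[a] || p[a] >= hi[a]) { ten = R_PosInf; break; }
      } else {
        double t1 = (lo[a] - p[a]) / u[a];
        double t2 = (hi[a] - p[a]) / u[a];
        double tlo = std::min(t1, t2), thi = std::max(t1, t2);
        if (tlo > ten) { ten = tlo; enter_axis = a; }
        if (thi < tex) tex = thi;
      }
    }
    if (ten > tex || ten > step) return false;
    if (ten > EPS_HIT && m0 == 0) {
      const double q[3] = {p[0] + (ten + EPS_HIT) * u[0],
                           p[1] + (ten + EPS_HIT) * u[1],
                           p[2] + (ten + EPS_HIT) * u[2]};
      const int m1 = material_at(q[0], q[1], q[2]);
      if (m1 != 0) {
        h.distance = ten;
        h.normal[0] = h.normal[1] = h.normal[2] = 0.0;
        h.normal[enter_axis] = (u[enter_axis] > 0) ? -1.0 : 1.0;
        h.before = 0; h.after = m1;
        return true;
      }
    }
    const double t0 = std::max(ten, 0.0);
    double iv[3];
    for (int a = 0; a < 3; ++a) {
      double st = p[a] + (t0 + EPS_HIT) * u[a];
      iv[a] = std::floor((st - lo[a]) / pitch);
      if (iv[a] < 0) iv[a] = 0;
      if (iv[a] > dims[a] - 1) iv[a] = dims[a] - 1;
    }
    double stepv[3], tmax[3], tdelta[3];
    for (int a = 0; a < 3; ++a) {
      stepv[a] = (u[a] > 0) ? 1.0 : ((u[a] < 0) ? -1.0 : 1.0);
      if (u[a] == 0) { tmax[a] = R_PosInf; tdelta[a] = R_PosInf; }
      else {
        double nextb = lo[a] + (iv[a] + (u[a] > 0 ? 1.0 : 0.0)) * pitch;
        tmax[a] = (nextb - p[a]) / u[a];
        tdelta[a] = pitch / std::fabs(u[a]);
      }
    }
    const double tend = std::min(step, tex);
    while (true) {
      int a = 0;
      if (tmax[1] < tmax[a]) a = 1;
      if (tmax[2] < tmax[a]) a = 2;
      const double t = tmax[a];
      if (t > tend) break;
      iv[a] += stepv[a];
      if (iv[0] < 0 || iv[1] < 0 || iv[2] < 0 ||
          iv[0] >= nx || iv[1] >= ny || iv[2] >= nz) {
        if (m0 != 0 && t <= step) {
          h.distance = t;
          h.normal[0] = h.normal[1] = h.normal[2] = 0.0;
          h.normal[a] = (u[a] > 0) ? -1.0 : 1.0;
          h.before = m0; h.after = 0;
          return true;
        }
        return false;
      }
      const int m1 = labels[(R_xlen_t)iv[0] +
                            nx * ((R_xlen_t)iv[1] + (R_xlen_t)ny * (R_xlen_t)iv[2])];
      if (m1 != m0) {
        h.distance = t;
        h.normal[0] = h.normal[1] = h.normal[2] = 0.0;
        h.normal[a] = (u[a] > 0) ? -1.0 : 1.0;
        h.before = m0; h.after = m1;
        return true;
      }
      tmax[a] += tdelta[a];
    }
    return false;
  }
};

// --------------------------------------------------------------- misc ----
static inline double clamp1(double x) {
  return x < -1.0 ? -1.0 : (x > 1.0 ? 1.0 : x);
}

// Unpolarized Fresnel reflectance from cos(theta1); matches the R-level
// fresnel_reflectance() up to the theta <-> cos(theta) parameterization.
static inline double fresnel_cos(double n1, double n2, double c1) {
  const double s1 = std::sqrt(1.0 - c1 * c1);
  const double s2 = n1 * s1 / n2;
  if (s2 >= 1.0) return 1.0;
  const double c2 = std::sqrt(1.0 - s2 * s2);
  const double rs = (n1 * c1 - n2 * c2) / (n1 * c1 + n2 * c2);
  const double rp = (n1 * c2 - n2 * c1) / (n1 * c2 + n2 * c1);
  return 0.5 * (rs * rs + rp * rp);
}

// first 0-based index with cdf > xi, or -1 if xi >= total
static inline int shift_index(const double* cdf, int K, double xi) {
  if (K == 0 || xi >= cdf[K - 1]) return -1;
  for (int i = 0; i < K; ++i)
    if (cdf[i] > xi) return i;
  return -1;  // unreachable
}

// deflect unit vector u by (cos/sin of polar angle, azimuth phi)
static inline void deflect(double* u, double ct, double st, double cp,
                           double sp) {
  double v0, v1, v2;
  if (std::fabs(u[2]) > 1.0 - 1e-12) {
    v0 = st * cp;
    v1 = st * sp;
    v2 = ct * (u[2] >= 0 ? 1.0 : -1.0);
  } else {
    const double den = std::sqrt(1.0 - u[2] * u[2]);
    v0 = st * (u[0] * u[2] * cp - u[1] * sp) / den + u[0] * ct;
    v1 = st * (u[1] * u[2] * cp + u[0] * sp) / den + u[1] * ct;
    v2 = -st * cp * den + u[2] * ct;
  }
  const double nrm = std::sqrt(v0 * v0 + v1 * v1 + v2 * v2);
  u[0] = v0 / nrm; u[1] = v1 / nrm; u[2] = v2 / nrm;
}

// ------------------------------------------------------------- engine ----
// [[Rcpp::export]]
List mc_batch_cpp(List geom_spec, List mat_spec, List source_spec,
                  List detector_spec, int n_photons, double seed, int batch,
                  int max_iter, int keep_mode, Nullable<List> replay,
                  bool record_variates, bool trace_depths) {
  // geometry
  Geom G;
  std::string kind = as<std::string>(geom_spec["kind"]);
  IntegerVector lab;  // keep voxel labels alive
  if (kind == "LAYERED") {
    G.kind = 0;
    G.zb = as<std::vector<double>>(geom_spec["boundaries"]);
    G.ids = as<std::vector<int>>(geom_spec["ids"]);
    G.hx = as<double>(geom_spec["half_x"]);
    G.hy = as<double>(geom_spec["half_y"]);
    const double ez = G.zb.back() - G.zb.front();
    G.reach = 2.0 * std::sqrt(4 * G.hx * G.hx + 4 * G.hy * G.hy + ez * ez) + 1.0;
  } else {
    G.kind = 1;
    lab = geom_spec["labels"];
    IntegerVector d = geom_spec["dims"];
    NumericVector o = geom_spec["origin"];
    G.labels = INTEGER(lab);
    G.nx = d[0]; G.ny = d[1]; G.nz = d[2];
    G.pitch = as<double>(geom_spec["pitch"]);
    G.ox = o[0]; G.oy = o[1]; G.oz = o[2];
    const double ex = G.nx * G.pitch, ey = G.ny * G.pitch, ez = G.nz * G.pitch;
    G.reach = 2.0 * std::sqrt(ex * ex + ey * ey + ez * ez) + 1.0;
  }

  // material property tables: K x nmat, column-major
  NumericMatrix MU_S = mat_spec["mu_s"], MU_A = mat_spec["mu_a"],
                GG = mat_spec["g"], NN = mat_spec["n"],
                CDF_R = mat_spec["cdf_R"], CDF_F = mat_spec["cdf_F"];
  const int K = MU_S.nrow();
  const int nmat = MU_S.ncol();
  const double *pMUS = REAL(MU_S), *pMUA = REAL(MU_A), *pG = REAL(GG),
               *pN = REAL(NN), *pCR = REAL(CDF_R), *pCF = REAL(CDF_F);

  // source
  const double src_std = as<double>(source_spec["std_mm"]);
  const double src_rad = as<double>(source_spec["radius_mm"]);
  const double cone_deg = as<double>(source_spec["cone_deg"]);
  const double src_z0 = as<double>(source_spec["z0_mm"]);
  const double src_cx = as<double>(source_spec["cx_mm"]);
  const double src_cy = as<double>(source_spec["cy_mm"]);
  const double cos_cone = std::cos(cone_deg * M_PI / 180.0);

  // detector (used when keep_mode == 1)
  double det_in = 0, det_out = 0, det_cosacc = -2, det_ztol = 1e-3,
         det_cx = 0, det_cy = 0;
  if (keep_mode == 1) {
    det_in = as<double>(detector_spec["inner_mm"]);
    det_out = as<double>(detector_spec["outer_mm"]);
    det_cosacc = std::cos(as<double>(detector_spec["accept_deg"]) * M_PI / 180.0);
    det_ztol = as<double>(detector_spec["z_tol_mm"]);
    det_cx = as<double>(detector_spec["cx_mm"]);
    det_cy = as<double>(detector_spec["cy_mm"]);
  }

  Stream st;
  uint64_t sd = (uint64_t)(int64_t)seed;
  sd ^= (uint64_t)(uint32_t)batch * 0xBF58476D1CE4E5B9ULL;
  st.rng.seed(sd);
  List rep_list;
  const bool do_replay = replay.isNotNull();
  if (do_replay) rep_list = replay.get();
  st.replay = do_replay;

  List var_out(record_variates ? n_photons : 0);
  std::vector<double> rec_buf;

  const int NCOL = 12;
  std::vector<double> out;  // row-major kept records
  out.reserve((size_t)std::min(n_photons, 100000) * NCOL);
  double n_abs = 0, n_esc = 0, n_cap = 0;
  // per-photon depths of every Raman conversion opportunity (one entry per
  // material-step xi6 draw); flushed into `traces` for kept photons only
  std::vector<double> cur_depths;
  std::vector<std::vector<double>> traces;

  for (int ph = 0; ph < n_photons; ++ph) {
    if ((ph & 0x3FFF) == 0) Rcpp::checkUserInterrupt();
    if (trace_depths) cur_depths.clear();
    NumericVector rv;
    if (do_replay) {
      rv = rep_list[ph];
      st.rep = REAL(rv); st.rep_n = rv.size(); st.rep_i = 0;
    }
    if (record_variates) { rec_buf.clear(); st.rec = &rec_buf; }

    // ---- launch ----
    double pos[3] = {src_cx, src_cy, -src_z0};
    if (src_std > 0) {
      double x, y;
      do {
        const double u1 = st.next(), u2 = st.next();
        const double r = src_std * std::sqrt(-2.0 * std::log(1.0 - u1));
        double cb, sb;
        cos_sin(TWOPI * u2, cb, sb);
        x = r * cb;
        y = r * sb;
      } while (src_rad > 0 && x * x + y * y > src_rad * src_rad);
      pos[0] += x; pos[1] += y;
    }
    double u[3] = {0.0, 0.0, 1.0};
    if (cone_deg > 0) {
      const double u3 = st.next(), u4 = st.next();
      const double ct = 1.0 - u3 * (1.0 - cos_cone);
      const double stq = std::sqrt(1.0 - ct * ct);
      const double phl = TWOPI * u4;
      double cl, sl;
      cos_sin(phl, cl, sl);
      u[0] = stq * cl; u[1] = stq * sl; u[2] = ct;
    }

    int wl = 0;  // 0-based grid index; 0 = source wavelength
    int n_raman = 0, n_fluor = 0;
    double raman_z = NA_REAL;
    int iters = 0, status = 0;
    // Raman conversion opportunities exist at collision sites (positions
    // reached by a completed free path or a fluorescence re-emission), not
    // at entry/boundary touch points where no material was traversed.
    bool at_collision = false;

    // ---- event loop ----
    while (true) {
      if (++iters > max_iter) { status = 3; break; }
      const int m = G.material_at(pos[0], pos[1], pos[2]);
      Hit h;
      if (m == 0) {  // void: straight propagation, boundary events only
        if (!G.first_interface(pos, u, G.reach, h)) { status = 2; break; }
        pos[0] += h.distance * u[0];
        pos[1] += h.distance * u[1];
        pos[2] += h.distance * u[2];
        const double c1 =
            clamp1(-(u[0] * h.normal[0] + u[1] * h.normal[1] + u[2] * h.normal[2]));
        const double n2 =
            (h.after == 0) ? 1.0 : pN[wl + (R_xlen_t)K * (h.after - 1)];
        const double R = fresnel_cos(1.0, n2, c1);
        const double xi7 = st.next();
        if (xi7 < R) {
          u[0] += 2.0 * c1 * h.normal[0];
          u[1] += 2.0 * c1 * h.normal[1];
          u[2] += 2.0 * c1 * h.normal[2];
        } else {
          const double eta = 1.0 / n2;
          const double c2 = std::sqrt(1.0 - eta * eta * (1.0 - c1 * c1));
          u[0] = eta * u[0] + (eta * c1 - c2) * h.normal[0];
          u[1] = eta * u[1] + (eta * c1 - c2) * h.normal[1];
          u[2] = eta * u[2] + (eta * c1 - c2) * h.normal[2];
        }
        const double nn = std::sqrt(u[0] * u[0] + u[1] * u[1] + u[2] * u[2]);
        u[0] /= nn; u[1] /= nn; u[2] /= nn;
        pos[0] += EPS_PUSH * u[0]; pos[1] += EPS_PUSH * u[1];
        pos[2] += EPS_PUSH * u[2];
        at_collision = false;
        continue;
      }
      const int mc = m - 1;  // material column
      const R_xlen_t mo = (R_xlen_t)K * mc;
      // (1) Raman check at the current collision site
      if (at_collision) {
        if (trace_depths) cur_depths.push_back(pos[2]);
        const double xi6 = st.next();
        const int kR = shift_index(pCR + mo, K, xi6);
        if (kR >= 0) {
          wl = kR;
          if (n_raman == 0) raman_z = pos[2];
          ++n_raman;
        }
      }
      const double mu_s = pMUS[wl + mo], mu_a = pMUA[wl + mo],
                   g = pG[wl + mo], n1 = pN[wl + mo];
      // (2) sample the free path; the photon hops along its current
      // direction and is deflected only at completed collision sites
      // (hop-drop-spin)
      const double xi1 = st.next();
      const double l = -std::log(1.0 - xi1) / mu_s;
      // (3) trace the segment, truncating at the first interface
      const bool hit = G.first_interface(pos, u, l, h);
      const double ltrav = hit ? h.distance : l;
      pos[0] += ltrav * u[0]; pos[1] += ltrav * u[1]; pos[2] += ltrav * u[2];
      // (4) absorption roulette over the traveled length
      const double xi4 = st.next();
      if (xi4 < 1.0 - std::exp(-mu_a * ltrav)) {
        // (5) fluorescence branch
        const double xi5 = st.next();
        const int kF = shift_index(pCF + mo, K, xi5);
        if (kF < 0) { status = 1; break; }
        wl = kF;
        ++n_fluor;
        const double xa = st.next(), xb = st.next();
        const double ctf = 2.0 * xa - 1.0;
        const double stf = std::sqrt(1.0 - ctf * ctf);
        const double phf = TWOPI * xb;
        double cf, sf;
        cos_sin(phf, cf, sf);
        u[0] = stf * cf; u[1] = stf * sf; u[2] = ctf;
        pos[0] += EPS_PUSH * u[0]; pos[1] += EPS_PUSH * u[1];
        pos[2] += EPS_PUSH * u[2];
        at_collision = true;
        continue;
      }
      if (!hit) {  // completed step: scatter at the new collision site
        const double xi2 = st.next();
        const double phi = TWOPI * xi2;
        const double xi3 = st.next();
        double ct;
        if (std::fabs(g) < 1e-6) {
          ct = 2.0 * xi3 - 1.0;
        } else {
          const double f = (1.0 - g * g) / (1.0 - g + 2.0 * g * xi3);
          ct = clamp1((1.0 + g * g - f * f) / (2.0 * g));
        }
        double cp, sp;
        cos_sin(phi, cp, sp);
        deflect(u, ct, std::sqrt(1.0 - ct * ct), cp, sp);
        at_collision = true;
      }
      if (hit) {  // Fresnel reflect/refract at the interface
        const double c1 =
            clamp1(-(u[0] * h.normal[0] + u[1] * h.normal[1] + u[2] * h.normal[2]));
        const double n2 =
            (h.after == 0) ? 1.0 : pN[wl + (R_xlen_t)K * (h.after - 1)];
        const double R = fresnel_cos(n1, n2, c1);
        const double xi7 = st.next();
        if (xi7 < R) {
          u[0] += 2.0 * c1 * h.normal[0];
          u[1] += 2.0 * c1 * h.normal[1];
          u[2] += 2.0 * c1 * h.normal[2];
        } else {
          const double eta = n1 / n2;
          const double c2 = std::sqrt(1.0 - eta * eta * (1.0 - c1 * c1));
          u[0] = eta * u[0] + (eta * c1 - c2) * h.normal[0];
          u[1] = eta * u[1] + (eta * c1 - c2) * h.normal[1];
          u[2] = eta * u[2] + (eta * c1 - c2) * h.normal[2];
        }
        const double nn = std::sqrt(u[0] * u[0] + u[1] * u[1] + u[2] * u[2]);
        u[0] /= nn; u[1] /= nn; u[2] /= nn;
        pos[0] += EPS_PUSH * u[0]; pos[1] += EPS_PUSH * u[1];
        pos[2] += EPS_PUSH * u[2];
        at_collision = false;
      }
    }

    if (status == 1) n_abs += 1;
    else if (status == 2) n_esc += 1;
    else n_cap += 1;

    bool keep = (keep_mode == 0);
    if (keep_mode == 1 && status == 2 && std::fabs(pos[2]) <= det_ztol &&
        u[2] < 0) {
      const double dx = pos[0] - det_cx, dy = pos[1] - det_cy;
      const double r = std::sqrt(dx * dx + dy * dy);
      if (r >= det_in && r < det_out && -u[2] >= det_cosacc) keep = true;
    }
    if (keep) {
      out.push_back((double)status);
      out.push_back(pos[0]); out.push_back(pos[1]); out.push_back(pos[2]);
      out.push_back(u[0]); out.push_back(u[1]); out.push_back(u[2]);
      out.push_back((double)(wl + 1));  // 1-based for R
      out.push_back((double)n_raman);
      out.push_back((double)n_fluor);
      out.push_back(raman_z);
      out.push_back((double)iters);
      if (trace_depths) traces.push_back(cur_depths);
    }
    if (record_variates) {
      var_out[ph] = NumericVector(rec_buf.begin(), rec_buf.end());
      st.rec = nullptr;
    }
  }

  const R_xlen_t nkept = (R_xlen_t)(out.size() / NCOL);
  NumericMatrix recs(nkept, NCOL);
  for (R_xlen_t i = 0; i < nkept; ++i)
    for (int j = 0; j < NCOL; ++j)
      recs(i, j) = out[i * NCOL + j];
  colnames(recs) =
      CharacterVector::create("status", "x", "y", "z", "ux", "uy", "uz",
                              "wl_index", "n_raman", "n_fluor", "raman_z",
                              "iterations");
  (void)nmat;
  List tr_out;
  if (trace_depths) {
    tr_out = List((R_xlen_t)traces.size());
    for (R_xlen_t i = 0; i < (R_xlen_t)traces.size(); ++i)
      tr_out[i] = NumericVector(traces[i].begin(), traces[i].end());
  }
  return List::create(
      _["records"] = recs,
      _["counts"] = NumericVector::create(
          _["launched"] = (double)n_photons, _["absorbed"] = n_abs,
          _["escaped"] = n_esc, _["iteration_cap"] = n_cap,
          _["kept"] = (double)nkept),
      _["variates"] = record_variates ? (SEXP)var_out : R_NilValue,
      _["depth_traces"] = trace_depths ? (SEXP)tr_out : R_NilValue);
}
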