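// Core molecular-dynamics kernels: pair potentials, neighbour lists,
// force/torque assembly, Beeman integration with constrained orientation
// dynamics, Nose-Hoover NVT thermostatting.
//
// All quantities are in reduced units (length sigma, energy eps, time t_s,
// unit masses and pseudo-masses). Positions are NOT wrapped: periodic
// boundaries enter only through minimum-image displacements, so recorded
// trajectories are already unwrapped in the periodic directions.
#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <unordered_set>
#include <algorithm>
using namespace Rcpp;

// particle type codes (match R constants in R/builder.R)
enum PType {
  T_LIPID_OUT = 1, T_LIPID_IN = 2, T_IMP_OUT = 3, T_IMP_IN = 4,
  T_TMP = 5, T_TMP_ANCH = 6, T_GPROT = 7, T_SPECTRIN = 8, T_ACTIN = 9
};

// pair interaction codes
enum PCode {
  C_NONE = 0,
  C_MEM = 1,      // orientation-dependent same-layer membrane pair
  C_LAYER = 2,    // inter-leaflet lipid-lipid cohesion
  C_SLIP = 3,     // spectrin-lipid shifted LJ (strength n)
  C_WCA = 4,      // truncated repulsive LJ steric, zero at its req
  C_SS = 5,       // spectrin-spectrin repulsion (scale 2 sigma)
  C_AA = 6        // actin-actin repulsion (minimum at req_aa)
};

struct FF {
  double k0, req_ss, eps1;
  double kA, req_aa, scale_aa;
  double kb, theta0, dthmax;
  double eps2, scale_as, capture_as;
  double kmt, deq_rr, ddmax;
  double rcut_mem, alpha, k_ll, k_lprot;
  double req_ll, req_lg, req_lp, req_pp;
  double k_layer, wc, rcut_layer;
  double n_sl, scale_sl, rcut_sl;
  double eps_steric;
  double eff[10];        // effective radius (sigma) per type code, steric use
  double skin;
};

static double getd(const List& ff, const char* nm) {
  if (!ff.containsElementNamed(nm)) stop("forcefield parameter '%s' missing", nm);
  return as<double>(ff[nm]);
}

static FF parseFF(const List& ff) {
  FF p;
  p.k0 = getd(ff, "k0"); p.req_ss = getd(ff, "req_ss"); p.eps1 = getd(ff, "eps1");
  p.kA = getd(ff, "kA"); p.req_aa = getd(ff, "req_aa");
  p.scale_aa = p.req_aa / std::pow(2.0, 1.0 / 6.0);
  p.kb = getd(ff, "kb"); p.theta0 = getd(ff, "theta0"); p.dthmax = getd(ff, "dthmax");
  p.eps2 = getd(ff, "eps2"); p.scale_as = getd(ff, "scale_as");
  p.capture_as = getd(ff, "capture_as");
  p.kmt = getd(ff, "kmt"); p.deq_rr = getd(ff, "deq_rr"); p.ddmax = getd(ff, "ddmax");
  p.rcut_mem = getd(ff, "rcut_mem"); p.alpha = getd(ff, "alpha");
  p.k_ll = getd(ff, "k_ll"); p.k_lprot = getd(ff, "k_lprot");
  p.req_ll = getd(ff, "req_ll"); p.req_lg = getd(ff, "req_lg");
  p.req_lp = getd(ff, "req_lp"); p.req_pp = getd(ff, "req_pp");
  p.k_layer = getd(ff, "k_layer"); p.wc = getd(ff, "wc");
  p.rcut_layer = getd(ff, "rcut_layer");
  p.n_sl = getd(ff, "n_sl"); p.scale_sl = getd(ff, "scale_sl");
  p.rcut_sl = getd(ff, "rcut_sl");
  p.eps_steric = getd(ff, "eps_steric");
  NumericVector eff = ff["eff_radius"];  // length 9, sigma units, by type code
  if (eff.size() != 9) stop("eff_radius must have 9 entries");
  p.eff[0] = 0.0;
  for (int t = 1; t <= 9; ++t) p.eff[t] = eff[t - 1];
  p.skin = getd(ff, "skin");
  return p;
}

struct Geom {
  // kind: 0 free, 1 slab (periodic x,y), 2 cylinder (periodic z)
  int kind;
  double box[3];
  bool per[3];
};

static Geom parseGeom(const List& g) {
  Geom gm;
  std::string kind = as<std::string>(g["kind"]);
  NumericVector box = g["box"];
  for (int d = 0; d < 3; ++d) { gm.box[d] = box[d]; gm.per[d] = false; }
  if (kind == "free") gm.kind = 0;
  else if (kind == "slab") { gm.kind = 1; gm.per[0] = gm.per[1] = true; }
  else if (kind == "cylinder") { gm.kind = 2; gm.per[2] = true; }
  else stop("unknown geometry kind '%s'", kind.c_str());
  return gm;
}

static inline void minImage(double* dx, const Geom& g) {
  for (int d = 0; d < 3; ++d)
    if (g.per[d]) dx[d] -= g.box[d] * std::round(dx[d] / g.box[d]);
}

static inline int layerMask(int t) {
  switch (t) {
    case T_LIPID_OUT: case T_IMP_OUT: return 1;
    case T_LIPID_IN:  case T_IMP_IN:  return 2;
    case T_TMP: case T_TMP_ANCH: case T_GPROT: return 3;
    default: return 0;
  }
}
static inline bool isLip(int t) { return t == T_LIPID_OUT || t == T_LIPID_IN; }
static inline bool isG(int t) { return t == T_GPROT; }
static inline bool isMem(int t) { return t >= 1 && t <= 7; }
static inline bool isSkel(int t) { return t == T_SPECTRIN || t == T_ACTIN; }

struct PairRule { int code; double k, req; };

// rotate vector v in place by the rotation vector phi (Rodrigues)
static inline void rotateBy(double* v, const double* phi) {
  double a = std::sqrt(phi[0]*phi[0] + phi[1]*phi[1] + phi[2]*phi[2]);
  if (a < 1e-14) return;
  double u[3] = { phi[0]/a, phi[1]/a, phi[2]/a };
  double c = std::cos(a), s = std::sin(a);
  double ud = u[0]*v[0] + u[1]*v[1] + u[2]*v[2];
  double cr[3] = { u[1]*v[2] - u[2]*v[1],
                   u[2]*v[0] - u[0]*v[2],
                   u[0]*v[1] - u[1]*v[0] };
  for (int d = 0; d < 3; ++d)
    v[d] = v[d]*c + cr[d]*s + u[d]*ud*(1.0 - c);
}

// classification of the non-bonded interaction for a type pair
static PairRule pairRule(int ti, int tj, const FF& ff) {
  PairRule r; r.code = C_NONE; r.k = 0; r.req = 0;
  if (isMem(ti) && isMem(tj)) {
    int mi = layerMask(ti), mj = layerMask(tj);
    if (mi & mj) {
      r.code = C_MEM;
      bool li = isLip(ti), lj = isLip(tj);
      r.k = (li && lj) ? ff.k_ll : ff.k_lprot;
      if (li && lj) r.req = ff.req_ll;
      else if ((li && isG(tj)) || (lj && isG(ti))) r.req = ff.req_lg;
      else if (li || lj) r.req = ff.req_lp;
      else r.req = ff.req_pp;  // protein-protein, G-protein, G-G
    } else if (isLip(ti) && isLip(tj)) {
      r.code = C_LAYER;
    }
    return r;
  }
  int ts = isSkel(ti) ? ti : tj;       // skeleton member of the pair
  int tm = isSkel(ti) ? tj : ti;       // the other one
  if (isSkel(ti) && isSkel(tj)) {
    if (ti == T_SPECTRIN && tj == T_SPECTRIN) { r.code = C_SS; return r; }
    if (ti == T_ACTIN && tj == T_ACTIN) { r.code = C_AA; return r; }
    r.code = C_WCA; r.req = ff.eff[T_SPECTRIN] + ff.eff[T_ACTIN];  // spectrin-actin steric
    return r;
  }
  if (!isSkel(ts)) return r;  // neither skeleton: handled above
  if (isLip(tm)) {
    if (ts == T_SPECTRIN && ff.n_sl > 0) r.code = C_SLIP;
    return r;  // actin-lipid: none
  }
  if (tm == T_IMP_OUT) return r;  // outer-leaflet IMPs have no cytosolic part
  if (tm == T_IMP_IN || tm == T_TMP || tm == T_TMP_ANCH || tm == T_GPROT) {
    r.code = C_WCA; r.req = ff.eff[ts] + ff.eff[tm];
    return r;
  }
  return r;
}

static double ruleCutoff(const PairRule& r, const FF& ff) {
  switch (r.code) {
    case C_MEM:   return ff.rcut_mem;
    case C_LAYER: return ff.rcut_layer + ff.wc;
    case C_SLIP:  return ff.rcut_sl;
    case C_WCA:   return r.req;
    case C_SS:    return ff.req_ss;
    case C_AA:    return ff.req_aa;
    default:      return 0.0;
  }
}

// ---------------------------------------------------------------------------
// scalar pair energy/force kernels (fpair = -dU/dr, positive = repulsive)

static inline void ljShift(double r, double eps, double s, double shift,
                           double& u, double& fpair) {
  double sr2 = (s * s) / (r * r);
  double sr6 = sr2 * sr2 * sr2, sr12 = sr6 * sr6;
  u = 4.0 * eps * (sr12 - sr6) + shift;
  fpair = 24.0 * eps * (2.0 * sr12 - sr6) / r;
}

struct Vec3 { double x, y, z; };

// Full orientation-dependent membrane pair. xh = unit vector from j to i.
static void memPair(double r, const double* ni, const double* nj,
                    const double* xh, double k, double req, const FF& ff,
                    double& u, double* f_i, double* g_i, double* g_j) {
  double denom = ff.rcut_mem - req;
  double z = (ff.rcut_mem - r) / denom;
  double z2 = z * z, z3 = z2 * z, z4 = z2 * z2, z7 = z4 * z3, z8 = z4 * z4;
  double uR = k * z8, uA = -2.0 * k * z4;
  double duR = -8.0 * k * z7 / denom, duA = 8.0 * k * z3 / denom;
  double nidnj = ni[0] * nj[0] + ni[1] * nj[1] + ni[2] * nj[2];
  double cni = ni[0] * xh[0] + ni[1] * xh[1] + ni[2] * xh[2];
  double cnj = nj[0] * xh[0] + nj[1] * xh[1] + nj[2] * xh[2];
  double a = nidnj - cni * cnj;
  double A = 1.0 + ff.alpha * (a - 1.0);
  u = uR + A * uA;
  double frad = -(duR + A * duA);
  double pref = -ff.alpha * uA / r;  // for the x-hat gradient of a
  for (int d = 0; d < 3; ++d) {
    // grad_i a = -[cnj*(ni - cni*xh) + cni*(nj - cnj*xh)]/r
    double da = -(cnj * (ni[d] - cni * xh[d]) + cni * (nj[d] - cnj * xh[d]));
    // f_i = -dU/dxi = frad*xh - alpha*uA*grad_i a, with grad_i a = da/r
    f_i[d] = frad * xh[d] + pref * da;
    g_i[d] = ff.alpha * uA * (nj[d] - cnj * xh[d]);
    g_j[d] = ff.alpha * uA * (ni[d] - cni * xh[d]);
  }
}

// ---------------------------------------------------------------------------
// neighbour lists

struct PairEntry { int i, j; PairRule rule; };

// cell-list enumeration of index pairs within cutoff among a subset of ids
static void cellPairs(const std::vector<double>& px, const std::vector<double>& py,
                      const std::vector<double>& pz, const std::vector<int>& ids,
                      const Geom& g, double cutoff,
                      std::vector<std::pair<int, int> >& out) {
  out.clear();
  int m = (int)ids.size();
  if (m < 2) return;
  double lo[3], hi[3], span[3];
  for (int d = 0; d < 3; ++d) {
    if (g.per[d]) { lo[d] = 0.0; span[d] = g.box[d]; }
    else {
      lo[d] = R_PosInf; hi[d] = R_NegInf;
      for (int a = 0; a < m; ++a) {
        double c = (d == 0 ? px[ids[a]] : (d == 1 ? py[ids[a]] : pz[ids[a]]));
        lo[d] = std::min(lo[d], c); hi[d] = std::max(hi[d], c);
      }
      span[d] = std::max(hi[d] - lo[d], 1e-9);
    }
  }
  int nc[3]; double cw[3];
  long ncells = 1;
  for (int d = 0; d < 3; ++d) {
    nc[d] = std::max(1, (int)std::floor(span[d] / cutoff));
    if (g.per[d] && nc[d] < 3) nc[d] = 1;  // degenerate: single cell, all pairs
    cw[d] = span[d] / nc[d];
    ncells *= nc[d];
  }
  std::vector<std::vector<int> > cells(ncells);
  std::vector<int> ci(m), cj(m), ck(m);
  for (int a = 0; a < m; ++a) {
    int id = ids[a];
    double c[3] = { px[id], py[id], pz[id] };
    int idx[3];
    for (int d = 0; d < 3; ++d) {
      double w = c[d] - lo[d];
      if (g.per[d]) w -= g.box[d] * std::floor(w / g.box[d]);
      int k = (int)std::floor(w / cw[d]);
      if (k < 0) k = 0; if (k >= nc[d]) k = nc[d] - 1;
      idx[d] = k;
    }
    ci[a] = idx[0]; cj[a] = idx[1]; ck[a] = idx[2];
    cells[(idx[0] * (long)nc[1] + idx[1]) * nc[2] + idx[2]].push_back(a);
  }
  double cut2 = cutoff * cutoff;
  for (int a = 0; a < m; ++a) {
    int ia = ids[a];
    for (int dx = -1; dx <= 1; ++dx)
      for (int dy = -1; dy <= 1; ++dy)
        for (int dz = -1; dz <= 1; ++dz) {
          int cx = ci[a] + dx, cy = cj[a] + dy, cz = ck[a] + dz;
          if (g.per[0] && nc[0] > 1) cx = (cx + nc[0]) % nc[0];
          if (g.per[1] && nc[1] > 1) cy = (cy + nc[1]) % nc[1];
          if (g.per[2] && nc[2] > 1) cz = (cz + nc[2]) % nc[2];
          if (cx < 0 || cx >= nc[0] || cy < 0 || cy >= nc[1] ||
              cz < 0 || cz >= nc[2]) continue;
          const std::vector<int>& cell = cells[(cx * (long)nc[1] + cy) * nc[2] + cz];
          for (size_t q = 0; q < cell.size(); ++q) {
            int b = cell[q];
            if (b <= a) continue;
            int ib = ids[b];
            double dd[3] = { px[ia] - px[ib], py[ia] - py[ib], pz[ia] - pz[ib] };
            minImage(dd, const_cast<Geom&>(g));
            double r2 = dd[0] * dd[0] + dd[1] * dd[1] + dd[2] * dd[2];
            if (r2 < cut2)
              out.push_back(std::make_pair(std::min(ia, ib), std::max(ia, ib)));
          }
        }
  }
  // cross-cell pairs are found from both sides, and a periodic dimension
  // with a single cell revisits itself; canonical order + dedupe
  std::sort(out.begin(), out.end());
  out.erase(std::unique(out.begin(), out.end()), out.end());
}

// ---------------------------------------------------------------------------
// simulation state

struct Sim {
  int n;
  std::vector<double> x, y, z;        // positions
  std::vector<double> nx, ny, nz;     // orientations (oriented particles)
  std::vector<int> type;
  std::vector<bool> oriented;
  Geom geom;
  FF ff;
  // bonded topology (0-based)
  std::vector<int> b_i, b_j; std::vector<double> b_k, b_req;
  std::vector<int> t_i; std::vector<double> t_x, t_y, t_z, t_k, t_req;
  std::vector<int> a_i, a_j, a_k;     // angle triples, a_j is the vertex
  std::vector<double> a_kb, a_th0, a_dth;
  std::vector<std::vector<int> > rings;
  std::vector<int> rp_a, rp_b; std::vector<double> rp_shift;
  std::vector<int> as_end;            // spectrin chain-end particles
  std::vector<int> as_partner;        // actin partner (-1 = broken)
  std::unordered_set<long long> excl; // spring-bonded pairs (steric exclusion)
  // neighbour machinery
  std::vector<PairEntry> listM, listS;
  std::vector<double> rx, ry, rz;     // positions at last rebuild
  long n_breaks;

  long long key(int i, int j) const {
    if (i > j) std::swap(i, j);
    return (long long)i * n + j;
  }

  void buildLists() {
    listM.clear(); listS.clear();
    // membrane-membrane short-range pairs via cell list
    std::vector<int> memIds, skelIds;
    for (int i = 0; i < n; ++i) {
      if (isMem(type[i])) memIds.push_back(i);
      if (isSkel(type[i])) skelIds.push_back(i);
    }
    double cutM = std::max(ff.rcut_mem, ff.rcut_layer + ff.wc) + ff.skin;
    std::vector<std::pair<int, int> > mp;
    cellPairs(x, y, z, memIds, geom, cutM, mp);
    for (size_t q = 0; q < mp.size(); ++q) {
      int i = mp[q].first, j = mp[q].second;
      PairRule r = pairRule(type[i], type[j], ff);
      if (r.code == C_NONE) continue;
      PairEntry e; e.i = i; e.j = j; e.rule = r;
      listM.push_back(e);
    }
    // skeleton-involving pairs, brute force over the (small) skeleton
    for (size_t a = 0; a < skelIds.size(); ++a) {
      int i = skelIds[a];
      for (int j = 0; j < n; ++j) {
        if (j == i) continue;
        if (isSkel(type[j]) && j < i) continue;  // skel-skel counted once
        PairRule r = pairRule(type[i], type[j], ff);
        if (r.code == C_NONE) continue;
        double cut = ruleCutoff(r, ff) + ff.skin;
        double dd[3] = { x[i] - x[j], y[i] - y[j], z[i] - z[j] };
        minImage(dd, geom);
        double r2 = dd[0] * dd[0] + dd[1] * dd[1] + dd[2] * dd[2];
        if (r2 >= cut * cut) continue;
        if (r.code == C_WCA && excl.count(key(i, j))) continue;
        PairEntry e; e.i = i; e.j = j; e.rule = r;
        listS.push_back(e);
      }
    }
    rx = x; ry = y; rz = z;
    reformBonds();
  }

  // broken spectrin-actin associations may reform with the nearest free
  // actin particle inside the capture radius (one spectrin end per actin)
  void reformBonds() {
    std::vector<char> occupied(n, 0);
    for (size_t e = 0; e < as_end.size(); ++e)
      if (as_partner[e] >= 0) occupied[as_partner[e]] = 1;
    for (size_t e = 0; e < as_end.size(); ++e) {
      if (as_partner[e] >= 0) continue;
      int i = as_end[e], best = -1; double bestr2 = ff.capture_as * ff.capture_as;
      for (int j = 0; j < n; ++j) {
        if (type[j] != T_ACTIN || occupied[j]) continue;
        double dd[3] = { x[i] - x[j], y[i] - y[j], z[i] - z[j] };
        minImage(dd, geom);
        double r2 = dd[0] * dd[0] + dd[1] * dd[1] + dd[2] * dd[2];
        if (r2 < bestr2) { bestr2 = r2; best = j; }
      }
      if (best >= 0) { as_partner[e] = best; occupied[best] = 1; }
    }
  }

  bool needRebuild() const {
    double lim2 = 0.25 * ff.skin * ff.skin;
    for (int i = 0; i < n; ++i) {
      double dx = x[i] - rx[i], dy = y[i] - ry[i], dz = z[i] - rz[i];
      if (dx * dx + dy * dy + dz * dz > lim2) return true;
    }
    return false;
  }

  // assemble forces (f*) and orientation gradients dV/dn (g*); returns energy
  double forces(std::vector<double>& fx, std::vector<double>& fy,
                std::vector<double>& fz, std::vector<double>& gx,
                std::vector<double>& gy, std::vector<double>& gz) {
    std::fill(fx.begin(), fx.end(), 0.0);
    std::fill(fy.begin(), fy.end(), 0.0);
    std::fill(fz.begin(), fz.end(), 0.0);
    std::fill(gx.begin(), gx.end(), 0.0);
    std::fill(gy.begin(), gy.end(), 0.0);
    std::fill(gz.begin(), gz.end(), 0.0);
    double U = 0.0;
    // --- non-bonded, membrane list
    for (size_t q = 0; q < listM.size(); ++q) {
      const PairEntry& e = listM[q];
      double dd[3] = { x[e.i] - x[e.j], y[e.i] - y[e.j], z[e.i] - z[e.j] };
      minImage(dd, geom);
      double r2 = dd[0] * dd[0] + dd[1] * dd[1] + dd[2] * dd[2];
      double r = std::sqrt(r2);
      if (e.rule.code == C_MEM) {
        if (r >= ff.rcut_mem) continue;
        if (r < 1e-12) stop("membrane pair at zero distance");
        double xh[3] = { dd[0] / r, dd[1] / r, dd[2] / r };
        double ni[3] = { nx[e.i], ny[e.i], nz[e.i] };
        double nj[3] = { nx[e.j], ny[e.j], nz[e.j] };
        double u, fi[3], gi[3], gj[3];
        memPair(r, ni, nj, xh, e.rule.k, e.rule.req, ff, u, fi, gi, gj);
        U += u;
        fx[e.i] += fi[0]; fy[e.i] += fi[1]; fz[e.i] += fi[2];
        fx[e.j] -= fi[0]; fy[e.j] -= fi[1]; fz[e.j] -= fi[2];
        gx[e.i] += gi[0]; gy[e.i] += gi[1]; gz[e.i] += gi[2];
        gx[e.j] += gj[0]; gy[e.j] += gj[1]; gz[e.j] += gj[2];
      } else {  // C_LAYER
        double u = 0, fp = 0;
        if (r < ff.rcut_layer) {
          if (r < 1e-12) stop("inter-layer pair at zero distance");
          ljShift(r, 1.0, 1.0, (1.0 - ff.k_layer), u, fp);
        } else if (r < ff.rcut_layer + ff.wc) {
          double phi = M_PI * (r - ff.rcut_layer) / (2.0 * ff.wc);
          double c = std::cos(phi);
          u = -ff.k_layer * c * c;
          fp = -ff.k_layer * std::sin(2.0 * phi) * M_PI / (2.0 * ff.wc);
        } else continue;
        U += u;
        double inv = fp / r;
        fx[e.i] += inv * dd[0]; fy[e.i] += inv * dd[1]; fz[e.i] += inv * dd[2];
        fx[e.j] -= inv * dd[0]; fy[e.j] -= inv * dd[1]; fz[e.j] -= inv * dd[2];
      }
    }
    // --- non-bonded, skeleton list
    for (size_t q = 0; q < listS.size(); ++q) {
      const PairEntry& e = listS[q];
      // live AS partner pairs are handled separately below
      double dd[3] = { x[e.i] - x[e.j], y[e.i] - y[e.j], z[e.i] - z[e.j] };
      minImage(dd, geom);
      double r = std::sqrt(dd[0] * dd[0] + dd[1] * dd[1] + dd[2] * dd[2]);
      double u = 0, fp = 0;
      switch (e.rule.code) {
        case C_SS:
          if (r >= ff.req_ss) continue;
          if (r < 1e-12) stop("spectrin pair at zero distance");
          ljShift(r, ff.eps1, 2.0, ff.eps1, u, fp);
          break;
        case C_AA:
          if (r >= ff.req_aa) continue;
          ljShift(r, ff.eps1, ff.scale_aa, ff.eps1, u, fp);
          break;
        case C_WCA:
          if (r >= e.rule.req) continue;
          if (isPartnerPair(e.i, e.j)) continue;
          ljShift(r, ff.eps_steric, e.rule.req / std::pow(2.0, 1.0 / 6.0),
                  ff.eps_steric, u, fp);
          break;
        case C_SLIP:
          if (r >= ff.rcut_sl) continue;
          ljShift(r, ff.n_sl, ff.scale_sl, ff.n_sl, u, fp);
          break;
        default: continue;
      }
      U += u;
      double inv = fp / r;
      fx[e.i] += inv * dd[0]; fy[e.i] += inv * dd[1]; fz[e.i] += inv * dd[2];
      fx[e.j] -= inv * dd[0]; fy[e.j] -= inv * dd[1]; fz[e.j] -= inv * dd[2];
    }
    // --- breakable actin-spectrin associations
    for (size_t e = 0; e < as_end.size(); ++e) {
      int jp = as_partner[e];
      if (jp < 0) continue;
      int i = as_end[e];
      double dd[3] = { x[i] - x[jp], y[i] - y[jp], z[i] - z[jp] };
      minImage(dd, geom);
      double r = std::sqrt(dd[0] * dd[0] + dd[1] * dd[1] + dd[2] * dd[2]);
      if (r > ff.capture_as) {  // bond breaks; force/energy zero beyond capture
        as_partner[e] = -1;
        n_breaks++;
        continue;
      }
      double u, fp;
      ljShift(r, ff.eps2, ff.scale_as, ff.eps2, u, fp);
      U += u;
      double inv = fp / r;
      fx[i] += inv * dd[0]; fy[i] += inv * dd[1]; fz[i] += inv * dd[2];
      fx[jp] -= inv * dd[0]; fy[jp] -= inv * dd[1]; fz[jp] -= inv * dd[2];
    }
    // --- springs
    for (size_t q = 0; q < b_i.size(); ++q) {
      int i = b_i[q], j = b_j[q];
      double dd[3] = { x[i] - x[j], y[i] - y[j], z[i] - z[j] };
      minImage(dd, geom);
      double r = std::sqrt(dd[0] * dd[0] + dd[1] * dd[1] + dd[2] * dd[2]);
      double dr = r - b_req[q];
      U += 0.5 * b_k[q] * dr * dr;
      if (r > 1e-12) {
        double inv = -b_k[q] * dr / r;
        fx[i] += inv * dd[0]; fy[i] += inv * dd[1]; fz[i] += inv * dd[2];
        fx[j] -= inv * dd[0]; fy[j] -= inv * dd[1]; fz[j] -= inv * dd[2];
      }
    }
    // --- tethers to fixed anchor points
    for (size_t q = 0; q < t_i.size(); ++q) {
      int i = t_i[q];
      double dd[3] = { x[i] - t_x[q], y[i] - t_y[q], z[i] - t_z[q] };
      minImage(dd, geom);
      double r = std::sqrt(dd[0] * dd[0] + dd[1] * dd[1] + dd[2] * dd[2]);
      double dr = r - t_req[q];
      U += 0.5 * t_k[q] * dr * dr;
      if (t_req[q] == 0.0) {
        fx[i] -= t_k[q] * dd[0]; fy[i] -= t_k[q] * dd[1]; fz[i] -= t_k[q] * dd[2];
      } else if (r > 1e-12) {
        double inv = -t_k[q] * dr / r;
        fx[i] += inv * dd[0]; fy[i] += inv * dd[1]; fz[i] += inv * dd[2];
      }
    }
    // --- FENE bending angles (vertex a_j)
    for (size_t q = 0; q < a_i.size(); ++q) {
      int i = a_i[q], j = a_j[q], k = a_k[q];
      double d1[3] = { x[i] - x[j], y[i] - y[j], z[i] - z[j] };
      double d2[3] = { x[k] - x[j], y[k] - y[j], z[k] - z[j] };
      minImage(d1, geom); minImage(d2, geom);
      double r1 = std::sqrt(d1[0] * d1[0] + d1[1] * d1[1] + d1[2] * d1[2]);
      double r2 = std::sqrt(d2[0] * d2[0] + d2[1] * d2[1] + d2[2] * d2[2]);
      double c = (d1[0] * d2[0] + d1[1] * d2[1] + d1[2] * d2[2]) / (r1 * r2);
      c = std::max(-1.0, std::min(1.0, c));
      double th = std::acos(c);
      double qq = (th - a_th0[q]) / a_dth[q];
      if (qq * qq >= 1.0)
        stop("FENE bending angle out of domain (|theta - theta0| >= dtheta_max)");
      U += -0.5 * a_kb[q] * a_dth[q] * std::log(1.0 - qq * qq);
      double dUdth = a_kb[q] * qq / (1.0 - qq * qq);
      double s = std::sqrt(std::max(1.0 - c * c, 1e-16));
      double co = dUdth / s;
      for (int d = 0; d < 3; ++d) {
        double u1 = d1[d] / r1, u2 = d2[d] / r2;
        double fi = co * (u2 - c * u1) / r1;
        double fk = co * (u1 - c * u2) / r2;
        (d == 0 ? fx : (d == 1 ? fy : fz))[i] += fi;
        (d == 0 ? fx : (d == 1 ? fy : fz))[k] += fk;
        (d == 0 ? fx : (d == 1 ? fy : fz))[j] -= fi + fk;
      }
    }
    // --- FENE ring-spacing (mean axial coordinate difference)
    if (!rp_a.empty()) {
      std::vector<double> zbar(rings.size());
      for (size_t r = 0; r < rings.size(); ++r) {
        double s = 0; for (size_t a = 0; a < rings[r].size(); ++a) s += z[rings[r][a]];
        zbar[r] = s / rings[r].size();
      }
      for (size_t q = 0; q < rp_a.size(); ++q) {
        int ra = rp_a[q], rb = rp_b[q];
        double d = (zbar[rb] + rp_shift[q]) - zbar[ra];
        double qq = (d - ff.deq_rr) / ff.ddmax;
        if (qq * qq >= 1.0)
          stop("FENE ring-spacing out of domain (|d - deq| >= dd_max)");
        U += -0.5 * ff.kmt * ff.ddmax * std::log(1.0 - qq * qq);
        double dUdd = ff.kmt * qq / (1.0 - qq * qq);
        double fa = dUdd / rings[ra].size(), fb = -dUdd / rings[rb].size();
        for (size_t a = 0; a < rings[ra].size(); ++a) fz[rings[ra][a]] += fa;
        for (size_t a = 0; a < rings[rb].size(); ++a) fz[rings[rb][a]] += fb;
      }
    }
    return U;
  }

  bool isPartnerPair(int i, int j) const {
    for (size_t e = 0; e < as_end.size(); ++e)
      if ((as_end[e] == i && as_partner[e] == j) ||
          (as_end[e] == j && as_partner[e] == i)) return true;
    return false;
  }
};

// Remove rigid-body zero modes from the velocities: the centre-of-mass
// drift always, the full angular momentum in free geometry, and the
// angular momentum about the cylinder axis in cylindrical geometry.
// Under a Nose-Hoover thermostat these uncoupled modes would otherwise
// accumulate kinetic energy (the "flying ice cube" artifact).
static void removeRigid(const Sim& s, std::vector<double>& vx,
                        std::vector<double>& vy, std::vector<double>& vz) {
  int n = s.n;
  if (n < 2) return;
  double cx = 0, cy = 0, cz = 0, mvx = 0, mvy = 0, mvz = 0;
  for (int i = 0; i < n; ++i) {
    cx += s.x[i]; cy += s.y[i]; cz += s.z[i];
    mvx += vx[i]; mvy += vy[i]; mvz += vz[i];
  }
  cx /= n; cy /= n; cz /= n; mvx /= n; mvy /= n; mvz /= n;
  for (int i = 0; i < n; ++i) { vx[i] -= mvx; vy[i] -= mvy; vz[i] -= mvz; }
  if (s.geom.kind == 1) return;  // slab: only linear drift is a zero mode
  if (s.geom.kind == 2) {
    // rotation about the cylinder (z) axis
    double Lz = 0, Iz = 0;
    for (int i = 0; i < n; ++i) {
      double dx = s.x[i] - cx, dy = s.y[i] - cy;
      Lz += dx * vy[i] - dy * vx[i];
      Iz += dx * dx + dy * dy;
    }
    if (Iz < 1e-12) return;
    double w = Lz / Iz;
    for (int i = 0; i < n; ++i) {
      double dx = s.x[i] - cx, dy = s.y[i] - cy;
      vx[i] += w * dy; vy[i] -= w * dx;
    }
    return;
  }
  // free geometry: full angular momentum about the centre of mass
  double L[3] = {0, 0, 0}, I[3][3] = {{0,0,0},{0,0,0},{0,0,0}};
  for (int i = 0; i < n; ++i) {
    double r[3] = { s.x[i] - cx, s.y[i] - cy, s.z[i] - cz };
    double v[3] = { vx[i], vy[i], vz[i] };
    L[0] += r[1]*v[2] - r[2]*v[1];
    L[1] += r[2]*v[0] - r[0]*v[2];
    L[2] += r[0]*v[1] - r[1]*v[0];
    double r2 = r[0]*r[0] + r[1]*r[1] + r[2]*r[2];
    for (int a = 0; a < 3; ++a)
      for (int b = 0; b < 3; ++b)
        I[a][b] += (a == b ? r2 : 0.0) - r[a]*r[b];
  }
  // solve I w = L (3x3, Gaussian elimination with small regularisation)
  double A[3][4];
  for (int a = 0; a < 3; ++a) {
    for (int b = 0; b < 3; ++b) A[a][b] = I[a][b] + (a == b ? 1e-10 : 0.0);
    A[a][3] = L[a];
  }
  for (int c = 0; c < 3; ++c) {
    int p = c;
    for (int r = c + 1; r < 3; ++r)
      if (std::fabs(A[r][c]) > std::fabs(A[p][c])) p = r;
    for (int b = 0; b < 4; ++b) std::swap(A[c][b], A[p][b]);
    if (std::fabs(A[c][c]) < 1e-14) return;
    for (int r = 0; r < 3; ++r) {
      if (r == c) continue;
      double f = A[r][c] / A[c][c];
      for (int b = c; b < 4; ++b) A[r][b] -= f * A[c][b];
    }
  }
  double w[3] = { A[0][3] / A[0][0], A[1][3] / A[1][1], A[2][3] / A[2][2] };
  for (int i = 0; i < n; ++i) {
    double r[3] = { s.x[i] - cx, s.y[i] - cy, s.z[i] - cz };
    vx[i] -= w[1]*r[2] - w[2]*r[1];
    vy[i] -= w[2]*r[0] - w[0]*r[2];
    vz[i] -= w[0]*r[1] - w[1]*r[0];
  }
}

static Sim makeSim(NumericMatrix pos, NumericMatrix orient, IntegerVector type,
                   List geom, List ff, List topo) {
  Sim s;
  s.n = pos.nrow();
  s.geom = parseGeom(geom);
  s.ff = parseFF(ff);
  s.n_breaks = 0;
  s.x.resize(s.n); s.y.resize(s.n); s.z.resize(s.n);
  s.nx.assign(s.n, 0.0); s.ny.assign(s.n, 0.0); s.nz.assign(s.n, 0.0);
  s.type.resize(s.n); s.oriented.resize(s.n);
  for (int i = 0; i < s.n; ++i) {
    s.x[i] = pos(i, 0); s.y[i] = pos(i, 1); s.z[i] = pos(i, 2);
    s.type[i] = type[i];
    s.oriented[i] = isMem(type[i]);
    if (s.oriented[i]) {
      s.nx[i] = orient(i, 0); s.ny[i] = orient(i, 1); s.nz[i] = orient(i, 2);
      double nn = std::sqrt(s.nx[i] * s.nx[i] + s.ny[i] * s.ny[i] + s.nz[i] * s.nz[i]);
      if (!(nn > 0.5)) stop("membrane particle %d lacks a unit orientation", i + 1);
      s.nx[i] /= nn; s.ny[i] /= nn; s.nz[i] /= nn;
    }
  }
  NumericMatrix bonds = topo["bonds"];
  for (int q = 0; q < bonds.nrow(); ++q) {
    s.b_i.push_back((int)bonds(q, 0) - 1);
    s.b_j.push_back((int)bonds(q, 1) - 1);
    s.b_k.push_back(bonds(q, 2));
    s.b_req.push_back(bonds(q, 3));
  }
  NumericMatrix teth = topo["tethers"];
  for (int q = 0; q < teth.nrow(); ++q) {
    s.t_i.push_back((int)teth(q, 0) - 1);
    s.t_x.push_back(teth(q, 1)); s.t_y.push_back(teth(q, 2));
    s.t_z.push_back(teth(q, 3));
    s.t_k.push_back(teth(q, 4)); s.t_req.push_back(teth(q, 5));
  }
  NumericMatrix ang = topo["angles"];
  for (int q = 0; q < ang.nrow(); ++q) {
    s.a_i.push_back((int)ang(q, 0) - 1);
    s.a_j.push_back((int)ang(q, 1) - 1);
    s.a_k.push_back((int)ang(q, 2) - 1);
    s.a_kb.push_back(ang(q, 3));
    s.a_th0.push_back(ang(q, 4));
    s.a_dth.push_back(ang(q, 5));
  }
  List rings = topo["rings"];
  for (int r = 0; r < rings.size(); ++r) {
    IntegerVector idx = rings[r];
    std::vector<int> v(idx.size());
    for (int a = 0; a < idx.size(); ++a) v[a] = idx[a] - 1;
    s.rings.push_back(v);
  }
  NumericMatrix rp = topo["ring_pairs"];
  for (int q = 0; q < rp.nrow(); ++q) {
    s.rp_a.push_back((int)rp(q, 0) - 1);
    s.rp_b.push_back((int)rp(q, 1) - 1);
    s.rp_shift.push_back(rp(q, 2));
  }
  IntegerVector ae = topo["as_ends"], ap = topo["as_partner"];
  for (int q = 0; q < ae.size(); ++q) {
    s.as_end.push_back(ae[q] - 1);
    s.as_partner.push_back(ap[q] - 1);  // 0 in R means unbonded -> -1
  }
  for (size_t q = 0; q < s.b_i.size(); ++q)
    s.excl.insert(s.key(s.b_i[q], s.b_j[q]));
  s.buildLists();
  return s;
}

// [[Rcpp::export]]
List cpp_forces(NumericMatrix pos, NumericMatrix orient, IntegerVector type,
                List geom, List ff, List topo) {
  Sim s = makeSim(pos, orient, type, geom, ff, topo);
  std::vector<double> fx(s.n), fy(s.n), fz(s.n), gx(s.n), gy(s.n), gz(s.n);
  double U = s.forces(fx, fy, fz, gx, gy, gz);
  NumericMatrix F(s.n, 3), G(s.n, 3);
  for (int i = 0; i < s.n; ++i) {
    F(i, 0) = fx[i]; F(i, 1) = fy[i]; F(i, 2) = fz[i];
    G(i, 0) = gx[i]; G(i, 1) = gy[i]; G(i, 2) = gz[i];
  }
  IntegerVector partner(s.as_partner.size());
  for (size_t e = 0; e < s.as_partner.size(); ++e) partner[e] = s.as_partner[e] + 1;
  return List::create(_["forces"] = F, _["orient_grad"] = G, _["energy"] = U,
                      _["as_partner"] = partner);
}

// [[Rcpp::export]]
IntegerMatrix cpp_neighbor_pairs(NumericMatrix pos, List geom, double cutoff) {
  Geom g = parseGeom(geom);
  int n = pos.nrow();
  std::vector<double> px(n), py(n), pz(n);
  std::vector<int> ids(n);
  for (int i = 0; i < n; ++i) {
    px[i] = pos(i, 0); py[i] = pos(i, 1); pz[i] = pos(i, 2); ids[i] = i;
  }
  std::vector<std::pair<int, int> > out;
  cellPairs(px, py, pz, ids, g, cutoff, out);
  IntegerMatrix m(out.size(), 2);
  for (size_t q = 0; q < out.size(); ++q) {
    int i = out[q].first, j = out[q].second;
    if (i > j) std::swap(i, j);
    m(q, 0) = i + 1; m(q, 1) = j + 1;
  }
  return m;
}

// [[Rcpp::export]]
List cpp_md_run(NumericMatrix pos, NumericMatrix orient, IntegerVector type,
                NumericMatrix vel, NumericMatrix avel,
                List geom, List ff, List topo,
                int n_steps, double dt, bool thermostat, double t_target,
                double tau_t, bool thermo_rot,
                int thermo_every, int traj_every, bool record_orient,
                int zero_com_every) {
  Sim s = makeSim(pos, orient, type, geom, ff, topo);
  int n = s.n;
  std::vector<double> vx(n), vy(n), vz(n), wx(n), wy(n), wz(n);
  for (int i = 0; i < n; ++i) {
    vx[i] = vel(i, 0); vy[i] = vel(i, 1); vz[i] = vel(i, 2);
    if (s.oriented[i]) { wx[i] = avel(i, 0); wy[i] = avel(i, 1); wz[i] = avel(i, 2); }
    else { wx[i] = wy[i] = wz[i] = 0.0; }
  }
  int n_or = 0;
  for (int i = 0; i < n; ++i) if (s.oriented[i]) n_or++;
  bool zero_modes = thermostat && zero_com_every > 0 && n >= 2;
  // translational DOF excluding the rigid modes held at zero; used both for
  // the thermostat target and the kinetic-temperature estimator
  double nf_trans = 3.0 * n -
    (zero_modes ? 3.0 + (s.geom.kind == 0 ? 3.0 : (s.geom.kind == 2 ? 1.0 : 0.0))
                : 0.0);
  nf_trans = std::max(nf_trans, 1.0);
  double nf = nf_trans + (thermo_rot ? 2.0 * n_or : 0.0);
  // Nose-Hoover chain of length 2 (better ergodicity than a single
  // thermostat for quasi-harmonic systems and soft collective modes);
  // masses follow the standard choice Q1 = nf*T*tau^2, Q2 = T*tau^2
  double Q1 = nf * t_target * tau_t * tau_t;
  double Q2 = t_target * tau_t * tau_t;
  double xi = 0.0, xi2 = 0.0;
  if (zero_modes) removeRigid(s, vx, vy, vz);

  std::vector<double> fx(n), fy(n), fz(n), gx(n), gy(n), gz(n);
  std::vector<double> ax(n), ay(n), az(n), bx_(n), by_(n), bz_(n);
  std::vector<double> anx(n), any_(n), anz(n), bnx(n), bny(n), bnz(n);

  // Rotational state: wx.. hold the angular velocity omega = n x n',
  // perpendicular to n; its equation of motion is m~ domega/dt = n x (-dV/dn),
  // equivalent to the constrained second-order equation for n. The
  // orientation itself advances by exact rotations, preserving |n| = 1.
  for (int i = 0; i < n; ++i) {
    if (!s.oriented[i]) { wx[i] = wy[i] = wz[i] = 0.0; continue; }
    double wdn = wx[i]*s.nx[i] + wy[i]*s.ny[i] + wz[i]*s.nz[i];
    wx[i] -= wdn * s.nx[i]; wy[i] -= wdn * s.ny[i]; wz[i] -= wdn * s.nz[i];
  }
  double U = s.forces(fx, fy, fz, gx, gy, gz);
  for (int i = 0; i < n; ++i) {
    ax[i] = fx[i] - (thermostat ? xi * vx[i] : 0.0);
    ay[i] = fy[i] - (thermostat ? xi * vy[i] : 0.0);
    az[i] = fz[i] - (thermostat ? xi * vz[i] : 0.0);
    if (s.oriented[i]) {
      anx[i] = -(s.ny[i]*gz[i] - s.nz[i]*gy[i]);
      any_[i] = -(s.nz[i]*gx[i] - s.nx[i]*gz[i]);
      anz[i] = -(s.nx[i]*gy[i] - s.ny[i]*gx[i]);
    } else anx[i] = any_[i] = anz[i] = 0.0;
  }
  bx_ = ax; by_ = ay; bz_ = az; bnx = anx; bny = any_; bnz = anz;

  // output buffers
  int n_frames = (traj_every > 0) ? (n_steps / traj_every + 1) : 0;
  int n_thermo = (thermo_every > 0) ? (n_steps / thermo_every + 1) : 0;
  NumericVector traj_t(std::max(n_frames, 0));
  IntegerVector traj_step(std::max(n_frames, 0));
  List frames(std::max(n_frames, 0)), oframes(record_orient ? std::max(n_frames, 0) : 0);
  NumericMatrix thermo(std::max(n_thermo, 0), 8);
  int fidx = 0, tidx = 0;
  const double dt2 = dt * dt;

  // helpers to record
  struct Rec {
    static void frame(const Sim& s, List& frames, List& oframes, NumericVector& tt,
                      IntegerVector& ts, int& fidx, int step, double dt,
                      bool record_orient) {
      int n = s.n;
      NumericMatrix P(n, 3);
      for (int i = 0; i < n; ++i) { P(i,0)=s.x[i]; P(i,1)=s.y[i]; P(i,2)=s.z[i]; }
      frames[fidx] = P;
      if (record_orient) {
        NumericMatrix O(n, 3);
        for (int i = 0; i < n; ++i) { O(i,0)=s.nx[i]; O(i,1)=s.ny[i]; O(i,2)=s.nz[i]; }
        oframes[fidx] = O;
      }
      tt[fidx] = step * dt; ts[fidx] = step; fidx++;
    }
  };

  double Kt = 0, Kr = 0;
  for (int i = 0; i < n; ++i) {
    Kt += 0.5 * (vx[i]*vx[i] + vy[i]*vy[i] + vz[i]*vz[i]);
    Kr += 0.5 * (wx[i]*wx[i] + wy[i]*wy[i] + wz[i]*wz[i]);
  }
  if (traj_every > 0)
    Rec::frame(s, frames, oframes, traj_t, traj_step, fidx, 0, dt, record_orient);
  if (thermo_every > 0) {
    thermo(tidx, 0) = 0; thermo(tidx, 1) = 0.0;
    thermo(tidx, 2) = 2.0 * Kt / nf_trans;
    thermo(tidx, 3) = n_or > 0 ? Kr / n_or : NA_REAL;
    thermo(tidx, 4) = U; thermo(tidx, 5) = U + Kt + Kr;
    thermo(tidx, 6) = xi; thermo(tidx, 7) = s.n_breaks;
    tidx++;
  }

  for (int step = 1; step <= n_steps; ++step) {
    // Beeman position update
    for (int i = 0; i < n; ++i) {
      s.x[i] += vx[i] * dt + (4.0 * ax[i] - bx_[i]) * dt2 / 6.0;
      s.y[i] += vy[i] * dt + (4.0 * ay[i] - by_[i]) * dt2 / 6.0;
      s.z[i] += vz[i] * dt + (4.0 * az[i] - bz_[i]) * dt2 / 6.0;
      if (s.oriented[i]) {
        double dphi[3] = {
          wx[i] * dt + (4.0 * anx[i] - bnx[i]) * dt2 / 6.0,
          wy[i] * dt + (4.0 * any_[i] - bny[i]) * dt2 / 6.0,
          wz[i] * dt + (4.0 * anz[i] - bnz[i]) * dt2 / 6.0 };
        double nv[3] = { s.nx[i], s.ny[i], s.nz[i] };
        rotateBy(nv, dphi);
        s.nx[i] = nv[0]; s.ny[i] = nv[1]; s.nz[i] = nv[2];
        // co-rotate the angular velocity: keeps it perpendicular to n to
        // higher order without discarding kinetic energy
        double wv[3] = { wx[i], wy[i], wz[i] };
        rotateBy(wv, dphi);
        wx[i] = wv[0]; wy[i] = wv[1]; wz[i] = wv[2];
      }
    }
    if (s.needRebuild()) s.buildLists();
    // predicted velocities (for the velocity-dependent friction term); the
    // thermostat itself is driven by the kinetic energy of the current
    // velocities, which is an unbiased estimate at equilibrium
    std::vector<double> vpx(n), vpy(n), vpz(n), wpx(n), wpy(n), wpz(n);
    double Kcur = 0.0;
    for (int i = 0; i < n; ++i) {
      vpx[i] = vx[i] + (3.0 * ax[i] - bx_[i]) * dt / 2.0;
      vpy[i] = vy[i] + (3.0 * ay[i] - by_[i]) * dt / 2.0;
      vpz[i] = vz[i] + (3.0 * az[i] - bz_[i]) * dt / 2.0;
      Kcur += 0.5 * (vx[i]*vx[i] + vy[i]*vy[i] + vz[i]*vz[i]);
      if (s.oriented[i]) {
        wpx[i] = wx[i] + (3.0 * anx[i] - bnx[i]) * dt / 2.0;
        wpy[i] = wy[i] + (3.0 * any_[i] - bny[i]) * dt / 2.0;
        wpz[i] = wz[i] + (3.0 * anz[i] - bnz[i]) * dt / 2.0;
        if (thermo_rot)
          Kcur += 0.5 * (wx[i]*wx[i] + wy[i]*wy[i] + wz[i]*wz[i]);
      } else wpx[i] = wpy[i] = wpz[i] = 0.0;
    }
    U = s.forces(fx, fy, fz, gx, gy, gz);
    if (thermostat) {
      double xi_old = xi;
      xi += dt * ((2.0 * Kcur - nf * t_target) / Q1 - xi * xi2);
      xi2 += dt * (Q1 * xi_old * xi_old - t_target) / Q2;
    }
    // new accelerations and velocity correction
    for (int i = 0; i < n; ++i) {
      double nax = fx[i] - (thermostat ? xi * vpx[i] : 0.0);
      double nay = fy[i] - (thermostat ? xi * vpy[i] : 0.0);
      double naz = fz[i] - (thermostat ? xi * vpz[i] : 0.0);
      vx[i] += (2.0 * nax + 5.0 * ax[i] - bx_[i]) * dt / 6.0;
      vy[i] += (2.0 * nay + 5.0 * ay[i] - by_[i]) * dt / 6.0;
      vz[i] += (2.0 * naz + 5.0 * az[i] - bz_[i]) * dt / 6.0;
      bx_[i] = ax[i]; by_[i] = ay[i]; bz_[i] = az[i];
      ax[i] = nax; ay[i] = nay; az[i] = naz;
      if (s.oriented[i]) {
        bool frict = thermostat && thermo_rot;
        double nanx = -(s.ny[i]*gz[i] - s.nz[i]*gy[i])
                      - (frict ? xi * wpx[i] : 0.0);
        double nany = -(s.nz[i]*gx[i] - s.nx[i]*gz[i])
                      - (frict ? xi * wpy[i] : 0.0);
        double nanz = -(s.nx[i]*gy[i] - s.ny[i]*gx[i])
                      - (frict ? xi * wpz[i] : 0.0);
        wx[i] += (2.0 * nanx + 5.0 * anx[i] - bnx[i]) * dt / 6.0;
        wy[i] += (2.0 * nany + 5.0 * any_[i] - bny[i]) * dt / 6.0;
        wz[i] += (2.0 * nanz + 5.0 * anz[i] - bnz[i]) * dt / 6.0;
        // drop the physically meaningless spin about the particle's own axis
        double wdn = wx[i]*s.nx[i] + wy[i]*s.ny[i] + wz[i]*s.nz[i];
        wx[i] -= wdn * s.nx[i]; wy[i] -= wdn * s.ny[i]; wz[i] -= wdn * s.nz[i];
        bnx[i] = anx[i]; bny[i] = any_[i]; bnz[i] = anz[i];
        anx[i] = nanx; any_[i] = nany; anz[i] = nanz;
      }
    }
    if (zero_modes && step % zero_com_every == 0)
      removeRigid(s, vx, vy, vz);
    if ((step & 1023) == 0) {
      for (int i = 0; i < n; ++i)
        if (!R_finite(s.x[i]) || !R_finite(vx[i]))
          stop("numerical blow-up (NaN/Inf) at step %d", step);
      Rcpp::checkUserInterrupt();
    }
    if (traj_every > 0 && step % traj_every == 0)
      Rec::frame(s, frames, oframes, traj_t, traj_step, fidx, step, dt, record_orient);
    if (thermo_every > 0 && step % thermo_every == 0) {
      Kt = Kr = 0.0;
      for (int i = 0; i < n; ++i) {
        Kt += 0.5 * (vx[i]*vx[i] + vy[i]*vy[i] + vz[i]*vz[i]);
        Kr += 0.5 * (wx[i]*wx[i] + wy[i]*wy[i] + wz[i]*wz[i]);
      }
      thermo(tidx, 0) = step; thermo(tidx, 1) = step * dt;
      thermo(tidx, 2) = 2.0 * Kt / nf_trans;
      thermo(tidx, 3) = n_or > 0 ? Kr / n_or : NA_REAL;
      thermo(tidx, 4) = U; thermo(tidx, 5) = U + Kt + Kr;
      thermo(tidx, 6) = xi; thermo(tidx, 7) = s.n_breaks;
      tidx++;
    }
  }

  NumericMatrix P(n, 3), O(n, 3), V(n, 3), W(n, 3);
  for (int i = 0; i < n; ++i) {
    P(i,0)=s.x[i]; P(i,1)=s.y[i]; P(i,2)=s.z[i];
    O(i,0)=s.nx[i]; O(i,1)=s.ny[i]; O(i,2)=s.nz[i];
    V(i,0)=vx[i]; V(i,1)=vy[i]; V(i,2)=vz[i];
    W(i,0)=wx[i]; W(i,1)=wy[i]; W(i,2)=wz[i];
  }
  IntegerVector partner(s.as_partner.size());
  for (size_t e = 0; e < s.as_partner.size(); ++e) partner[e] = s.as_partner[e] + 1;
  colnames(thermo) = CharacterVector::create("step", "time", "temp_trans",
    "ke_rot_per_particle", "potential", "total_energy", "xi", "n_breaks");
  return List::create(
    _["pos"] = P, _["orient"] = O, _["vel"] = V, _["avel"] = W,
    _["frames"] = frames, _["orient_frames"] = oframes,
    _["frame_time"] = traj_t, _["frame_step"] = traj_step,
    _["thermo"] = thermo, _["n_breaks"] = (double)s.n_breaks,
    _["as_partner"] = partner, _["xi"] = xi);
}
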