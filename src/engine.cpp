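// Core numerical kernels: neighbour lists, nonbonded (LJ + reaction-field)
// and bonded interactions, SETTLE/SHAKE constraints, and the leapfrog MD
// step loop with the three-bath weak-coupling thermostat.
//
// Units throughout: nm, ps, u (g/mol), K, kJ/mol, elementary charge.
// All atom indices arriving from R are 1-based and converted here.

#include <Rcpp.h>
#include <unordered_set>
#include <vector>
#include <cmath>
#include <cstdint>

using namespace Rcpp;

static const double KB = 0.00831446;      // kJ/(mol K)
static const double FEL = 138.935458;     // kJ nm/(mol e^2), 1/(4 pi eps0)
static const double P_UNIT = 16.3885;     // kJ/(mol nm^3) -> atm

// ---------------------------------------------------------------------------
// small helpers

static inline double dot3(const double* a, const double* b) {
  return a[0] * b[0] + a[1] * b[1] + a[2] * b[2];
}
static inline void cross3(const double* a, const double* b, double* c) {
  c[0] = a[1] * b[2] - a[2] * b[1];
  c[1] = a[2] * b[0] - a[0] * b[2];
  c[2] = a[0] * b[1] - a[1] * b[0];
}
static inline double norm3(const double* a) { return std::sqrt(dot3(a, a)); }

static inline int64_t pair_key(int i, int j, int n) {
  if (i > j) std::swap(i, j);
  return (int64_t)i * (int64_t)n + (int64_t)j;
}

struct ExclSet {
  std::unordered_set<int64_t> s;
  int n;
  bool has(int i, int j) const { return s.count(pair_key(i, j, n)) > 0; }
};

static ExclSet make_exclset(const IntegerMatrix& excl, int natoms) {
  ExclSet e;
  e.n = natoms;
  for (int k = 0; k < excl.nrow(); ++k)
    e.s.insert(pair_key(excl(k, 0) - 1, excl(k, 1) - 1, natoms));
  return e;
}

// ---------------------------------------------------------------------------
// pair list (charge-group / molecule based cutoff with periodic shifts)

// Pair list organized as group-pair records over expanded site pairs.
// The cutoff acts between group (charge-group/molecule) centres of
// geometry, and the whole site-site interaction of a group pair is
// modulated by a smooth switching function of the centre distance, so the
// potential is C1-continuous when pairs cross the cutoff.
struct PairList {
  // per group pair
  std::vector<int> gp_i, gp_j;               // group ids
  std::vector<int> gp_mx, gp_my, gp_mz;      // image multiples applied to j
  std::vector<int> gp_grp;                   // 0 pp, 1 pw, 2 ss
  std::vector<int> gp_start;                 // first site-pair index; size ngp+1
  // per site pair
  std::vector<int> i, j;
  std::vector<double> qq, c6, c12;
};

struct Groups {
  int ngrp;
  std::vector<std::vector<int> > members;
  std::vector<double> cx, cy, cz;            // centres of geometry
  void init(const std::vector<int>& gid, int n) {
    ngrp = 0;
    for (int a = 0; a < n; ++a) if (gid[a] + 1 > ngrp) ngrp = gid[a] + 1;
    members.assign(ngrp, std::vector<int>());
    for (int a = 0; a < n; ++a) members[gid[a]].push_back(a);
    cx.assign(ngrp, 0.0); cy.assign(ngrp, 0.0); cz.assign(ngrp, 0.0);
  }
  void update_centres(const std::vector<double>& x) {
    for (int g = 0; g < ngrp; ++g) {
      double sx = 0, sy = 0, sz = 0;
      for (size_t k = 0; k < members[g].size(); ++k) {
        int a = members[g][k];
        sx += x[3 * a]; sy += x[3 * a + 1]; sz += x[3 * a + 2];
      }
      double inv = 1.0 / (double)members[g].size();
      cx[g] = sx * inv; cy[g] = sy * inv; cz[g] = sz * inv;
    }
  }
};

static void build_group_pairlist(const std::vector<double>& x,
                                 const double* box, double rlist,
                                 Groups& grps,
                                 const std::vector<int>& egrp,
                                 const std::vector<double>& charge,
                                 const std::vector<int>& type,
                                 const NumericMatrix& c6tab,
                                 const NumericMatrix& c12tab,
                                 const ExclSet& excl, PairList& pl) {
  grps.update_centres(x);
  pl.gp_i.clear(); pl.gp_j.clear();
  pl.gp_mx.clear(); pl.gp_my.clear(); pl.gp_mz.clear();
  pl.gp_grp.clear(); pl.gp_start.clear();
  pl.i.clear(); pl.j.clear(); pl.qq.clear(); pl.c6.clear(); pl.c12.clear();
  double rl2 = rlist * rlist;
  int ngrp = grps.ngrp;
  for (int g1 = 0; g1 < ngrp; ++g1) {
    for (int g2 = g1 + 1; g2 < ngrp; ++g2) {
      double dx = grps.cx[g1] - grps.cx[g2];
      double dy = grps.cy[g1] - grps.cy[g2];
      double dz = grps.cz[g1] - grps.cz[g2];
      int mx = (int)std::lround(dx / box[0]);
      int my = (int)std::lround(dy / box[1]);
      int mz = (int)std::lround(dz / box[2]);
      dx -= mx * box[0]; dy -= my * box[1]; dz -= mz * box[2];
      if (dx * dx + dy * dy + dz * dz > rl2) continue;
      int nsite_before = (int)pl.i.size();
      for (size_t a = 0; a < grps.members[g1].size(); ++a) {
        int ia = grps.members[g1][a];
        for (size_t b = 0; b < grps.members[g2].size(); ++b) {
          int jb = grps.members[g2][b];
          if (excl.has(ia, jb)) continue;
          pl.i.push_back(ia); pl.j.push_back(jb);
          pl.qq.push_back(FEL * charge[ia] * charge[jb]);
          pl.c6.push_back(c6tab(type[ia], type[jb]));
          pl.c12.push_back(c12tab(type[ia], type[jb]));
        }
      }
      if ((int)pl.i.size() == nsite_before) continue;
      pl.gp_i.push_back(g1); pl.gp_j.push_back(g2);
      pl.gp_mx.push_back(mx); pl.gp_my.push_back(my); pl.gp_mz.push_back(mz);
      int eg1 = egrp[grps.members[g1][0]];
      int eg2 = egrp[grps.members[g2][0]];
      pl.gp_grp.push_back(eg1 + eg2);
      pl.gp_start.push_back(nsite_before);
    }
  }
  pl.gp_start.push_back((int)pl.i.size());
}

// CHARMM-style switching of the group-pair interaction between rs and rc:
// S = 1 below rs, 0 above rc, C1-continuous in between.
static inline void switch_fn(double r, double rs, double rc, double& S,
                             double& dSdr) {
  if (r <= rs) { S = 1.0; dSdr = 0.0; return; }
  if (r >= rc) { S = 0.0; dSdr = 0.0; return; }
  double rc2 = rc * rc, rs2 = rs * rs, r2 = r * r;
  double denom = (rc2 - rs2); denom = denom * denom * denom;
  double a = rc2 - r2;
  S = a * a * (rc2 + 2.0 * r2 - 3.0 * rs2) / denom;
  dSdr = 12.0 * r * a * (rs2 - r2) / denom;
}

// ---------------------------------------------------------------------------
// nonbonded energies/forces from a pair list

struct NbEnergies {
  double evdw[3];  // pp, pw, ss
  double ees[3];
  NbEnergies() { evdw[0] = evdw[1] = evdw[2] = 0; ees[0] = ees[1] = ees[2] = 0; }
};

static void nonbonded_eval(const PairList& pl, const std::vector<double>& x,
                           const double* box, Groups& grps, double rc,
                           double rswitch, double crf, std::vector<double>& f,
                           NbEnergies& en, double& virial) {
  grps.update_centres(x);
  double rc3 = rc * rc * rc;
  double crf_half = 1.0 + 0.5 * crf;
  int ngp = (int)pl.gp_i.size();
  for (int gp = 0; gp < ngp; ++gp) {
    int g1 = pl.gp_i[gp], g2 = pl.gp_j[gp];
    double Rx = grps.cx[g1] - (grps.cx[g2] + pl.gp_mx[gp] * box[0]);
    double Ry = grps.cy[g1] - (grps.cy[g2] + pl.gp_my[gp] * box[1]);
    double Rz = grps.cz[g1] - (grps.cz[g2] + pl.gp_mz[gp] * box[2]);
    double R = std::sqrt(Rx * Rx + Ry * Ry + Rz * Rz);
    if (R >= rc) continue;
    double S, dSdr;
    switch_fn(R, rswitch, rc, S, dSdr);
    double u_vdw = 0.0, u_es = 0.0;
    int g = pl.gp_grp[gp];
    for (int k = pl.gp_start[gp]; k < pl.gp_start[gp + 1]; ++k) {
      int i = pl.i[k], j = pl.j[k];
      double dx = x[3 * i] - (x[3 * j] + pl.gp_mx[gp] * box[0]);
      double dy = x[3 * i + 1] - (x[3 * j + 1] + pl.gp_my[gp] * box[1]);
      double dz = x[3 * i + 2] - (x[3 * j + 2] + pl.gp_mz[gp] * box[2]);
      double r2 = dx * dx + dy * dy + dz * dz;
      if (r2 < 1e-12)
        stop("atom overlap between atoms %d and %d (r < 1e-6 nm)", i + 1, j + 1);
      double invr2 = 1.0 / r2;
      double ir6 = invr2 * invr2 * invr2;
      double c6 = pl.c6[k], c12 = pl.c12[k], qq = pl.qq[k];
      double elj = c12 * ir6 * ir6 - c6 * ir6;
      double fscal = (12.0 * c12 * ir6 * ir6 - 6.0 * c6 * ir6) * invr2;
      double r = std::sqrt(r2);
      double invr = 1.0 / r;
      double ees = qq * (invr + crf * r2 / (2.0 * rc3) - crf_half / rc);
      fscal += qq * (invr * invr2 - crf / rc3);
      fscal *= S;
      u_vdw += elj;
      u_es += ees;
      virial += fscal * r2;
      double fx = fscal * dx, fy = fscal * dy, fz = fscal * dz;
      f[3 * i] += fx; f[3 * i + 1] += fy; f[3 * i + 2] += fz;
      f[3 * j] -= fx; f[3 * j + 1] -= fy; f[3 * j + 2] -= fz;
    }
    en.evdw[g] += S * u_vdw;
    en.ees[g] += S * u_es;
    if (dSdr != 0.0) {
      // centre-of-geometry force from the switching envelope
      double U = u_vdw + u_es;
      double pref = -U * dSdr / R;               // force = -U S'(R) unitR
      double Fx = pref * Rx, Fy = pref * Ry, Fz = pref * Rz;
      double inv1 = 1.0 / (double)grps.members[g1].size();
      double inv2 = 1.0 / (double)grps.members[g2].size();
      for (size_t a = 0; a < grps.members[g1].size(); ++a) {
        int ia = grps.members[g1][a];
        f[3 * ia] += Fx * inv1; f[3 * ia + 1] += Fy * inv1; f[3 * ia + 2] += Fz * inv1;
      }
      for (size_t b = 0; b < grps.members[g2].size(); ++b) {
        int jb = grps.members[g2][b];
        f[3 * jb] -= Fx * inv2; f[3 * jb + 1] -= Fy * inv2; f[3 * jb + 2] -= Fz * inv2;
      }
      virial += (Fx * Rx + Fy * Ry + Fz * Rz);
    }
  }
}

// reaction-field correction for excluded pairs (GROMOS convention): the
// mean-field term beyond 1/r acts inside exclusions too. Only the
// distance-dependent part crf r^2/(2 Rc^3) is accumulated; the constant
// shift -(1+crf/2)/Rc exists to cancel the direct 1/r at the cutoff and
// has no counterpart for excluded pairs (and no force).
static void excluded_rf_eval(const IntegerMatrix& excl, const std::vector<double>& x,
                             const double* box, double rc, double crf,
                             const std::vector<double>& charge,
                             const std::vector<int>& egrp,
                             std::vector<double>& f, NbEnergies& en,
                             double& virial) {
  double rc3 = rc * rc * rc;
  for (int k = 0; k < excl.nrow(); ++k) {
    int i = excl(k, 0) - 1, j = excl(k, 1) - 1;
    double dx = x[3 * i] - x[3 * j];
    double dy = x[3 * i + 1] - x[3 * j + 1];
    double dz = x[3 * i + 2] - x[3 * j + 2];
    dx -= box[0] * std::lround(dx / box[0]);
    dy -= box[1] * std::lround(dy / box[1]);
    dz -= box[2] * std::lround(dz / box[2]);
    double r2 = dx * dx + dy * dy + dz * dz;
    double qq = FEL * charge[i] * charge[j];
    double ees = qq * crf * r2 / (2.0 * rc3);
    double fscal = -qq * crf / rc3;
    int g = egrp[i] + egrp[j];
    en.ees[g] += ees;
    virial += fscal * r2;
    double fx = fscal * dx, fy = fscal * dy, fz = fscal * dz;
    f[3 * i] += fx; f[3 * i + 1] += fy; f[3 * i + 2] += fz;
    f[3 * j] -= fx; f[3 * j + 1] -= fy; f[3 * j + 2] -= fz;
  }
}

// ---------------------------------------------------------------------------
// bonded terms (no periodic imaging: bonded molecules are kept whole)

static double bonds_eval(const IntegerMatrix& bonds, const NumericVector& r0,
                         const NumericVector& kb, const std::vector<double>& x,
                         std::vector<double>& f, double& virial) {
  double e = 0.0;
  for (int k = 0; k < bonds.nrow(); ++k) {
    int i = bonds(k, 0) - 1, j = bonds(k, 1) - 1;
    double d[3] = { x[3 * i] - x[3 * j], x[3 * i + 1] - x[3 * j + 1],
                    x[3 * i + 2] - x[3 * j + 2] };
    double r = norm3(d);
    double dr = r - r0[k];
    e += 0.5 * kb[k] * dr * dr;
    double fscal = -kb[k] * dr / r;
    virial += fscal * r * r;
    for (int c = 0; c < 3; ++c) {
      f[3 * i + c] += fscal * d[c];
      f[3 * j + c] -= fscal * d[c];
    }
  }
  return e;
}

static double angles_eval(const IntegerMatrix& angles, const NumericVector& th0,
                          const NumericVector& kth, const std::vector<double>& x,
                          std::vector<double>& f, double& virial) {
  double e = 0.0;
  for (int k = 0; k < angles.nrow(); ++k) {
    int i = angles(k, 0) - 1, j = angles(k, 1) - 1, l = angles(k, 2) - 1;
    double rij[3], rkj[3];
    for (int c = 0; c < 3; ++c) {
      rij[c] = x[3 * i + c] - x[3 * j + c];
      rkj[c] = x[3 * l + c] - x[3 * j + c];
    }
    double nij = norm3(rij), nkj = norm3(rkj);
    double cth = dot3(rij, rkj) / (nij * nkj);
    if (cth > 1.0) cth = 1.0;
    if (cth < -1.0) cth = -1.0;
    double sth = std::sqrt(1.0 - cth * cth);
    if (sth < 1e-8)
      stop("degenerate (collinear) angle %d-%d-%d", i + 1, j + 1, l + 1);
    double th = std::acos(cth);
    double dth = th - th0[k];
    e += 0.5 * kth[k] * dth * dth;
    double dVdth = kth[k] * dth;
    double fi[3], fl[3];
    for (int c = 0; c < 3; ++c) {
      // dtheta/dx_i = -(v - cos u)/(|rij| sin); F_i = -dV/dtheta * dtheta/dx_i
      fi[c] = dVdth / (nij * sth) * (rkj[c] / nkj - cth * rij[c] / nij);
      fl[c] = dVdth / (nkj * sth) * (rij[c] / nij - cth * rkj[c] / nkj);
      f[3 * i + c] += fi[c];
      f[3 * l + c] += fl[c];
      f[3 * j + c] -= fi[c] + fl[c];
    }
    virial += dot3(fi, rij) + dot3(fl, rkj);
  }
  return e;
}

static double dihedrals_eval(const IntegerMatrix& dih, const IntegerVector& mult,
                             const NumericVector& phi0, const NumericVector& kphi,
                             const std::vector<double>& x, std::vector<double>& f,
                             double& virial) {
  double e = 0.0;
  for (int k = 0; k < dih.nrow(); ++k) {
    int i = dih(k, 0) - 1, j = dih(k, 1) - 1, l = dih(k, 2) - 1, m = dih(k, 3) - 1;
    double rij[3], rkj[3], rkl[3];
    for (int c = 0; c < 3; ++c) {
      rij[c] = x[3 * i + c] - x[3 * j + c];
      rkj[c] = x[3 * l + c] - x[3 * j + c];
      rkl[c] = x[3 * l + c] - x[3 * m + c];
    }
    double mv[3], nv[3];
    cross3(rij, rkj, mv);
    cross3(rkj, rkl, nv);
    double nrkj = norm3(rkj);
    double iprm = dot3(mv, mv), iprn = dot3(nv, nv);
    if (iprm < 1e-16 || iprn < 1e-16)
      stop("degenerate dihedral %d-%d-%d-%d", i + 1, j + 1, l + 1, m + 1);
    double cx[3];
    cross3(mv, nv, cx);
    double phi = std::atan2(dot3(cx, rkj) / nrkj, dot3(mv, nv));
    e += kphi[k] * (1.0 + std::cos(mult[k] * phi - phi0[k]));
    double ddphi = -kphi[k] * mult[k] * std::sin(mult[k] * phi - phi0[k]);
    double fi[3], fl4[3];
    for (int c = 0; c < 3; ++c) {
      fi[c] = -ddphi * nrkj / iprm * mv[c];
      fl4[c] = ddphi * nrkj / iprn * nv[c];
    }
    double p = dot3(rij, rkj) / (nrkj * nrkj);
    double q = dot3(rkl, rkj) / (nrkj * nrkj);
    double sv[3];
    for (int c = 0; c < 3; ++c) sv[c] = p * fi[c] - q * fl4[c];
    for (int c = 0; c < 3; ++c) {
      f[3 * i + c] += fi[c];
      f[3 * j + c] += sv[c] - fi[c];
      f[3 * l + c] += -sv[c] - fl4[c];
      f[3 * m + c] += fl4[c];
    }
    // torsion forces are internal; virial via sum f.r over the four atoms
    virial += dot3(fi, rij) - dot3(fl4, rkl);
  }
  return e;
}

static double restraints_eval(const IntegerVector& idx, const NumericMatrix& xref,
                              double kres, const std::vector<double>& x,
                              std::vector<double>& f) {
  double e = 0.0;
  for (int k = 0; k < idx.size(); ++k) {
    int i = idx[k] - 1;
    for (int c = 0; c < 3; ++c) {
      double d = x[3 * i + c] - xref(k, c);
      e += 0.5 * kres * d * d;
      f[3 * i + c] += -kres * d;
    }
  }
  return e;
}

// ---------------------------------------------------------------------------
// constraints

// iterative SHAKE on a set of distance constraints; returns iterations used,
// -1 on failure. tol is relative on distance.
static int shake_run(const std::vector<double>& xref, std::vector<double>& x,
                     const IntegerMatrix& cons, const NumericVector& d0,
                     const std::vector<double>& invmass, double tol, int maxit,
                     int* bad_bond) {
  int nc = cons.nrow();
  for (int it = 0; it < maxit; ++it) {
    bool done = true;
    for (int k = 0; k < nc; ++k) {
      int i = cons(k, 0) - 1, j = cons(k, 1) - 1;
      double d[3] = { x[3 * i] - x[3 * j], x[3 * i + 1] - x[3 * j + 1],
                      x[3 * i + 2] - x[3 * j + 2] };
      double r2 = dot3(d, d);
      double diff = r2 - d0[k] * d0[k];
      if (std::fabs(std::sqrt(r2) - d0[k]) > tol * d0[k]) {
        done = false;
        double dref[3] = { xref[3 * i] - xref[3 * j],
                           xref[3 * i + 1] - xref[3 * j + 1],
                           xref[3 * i + 2] - xref[3 * j + 2] };
        double den = 2.0 * (invmass[i] + invmass[j]) * dot3(dref, d);
        if (std::fabs(den) < 1e-12) { if (bad_bond) *bad_bond = k; return -1; }
        double g = diff / den;
        for (int c = 0; c < 3; ++c) {
          x[3 * i + c] -= g * invmass[i] * dref[c];
          x[3 * j + c] += g * invmass[j] * dref[c];
        }
      }
    }
    if (done) return it;
  }
  if (bad_bond) *bad_bond = -1;
  return -1;
}

// analytic SETTLE (Miyamoto & Kollman) for one rigid 3-site water.
// ref: constraint-satisfying positions at t; x: unconstrained positions at
// t+dt; indices o,h1,h2 are 0-based. Geometry: dOH, dHH. Returns false if the
// configuration is degenerate (caller falls back to SHAKE).
static bool settle_one(const std::vector<double>& ref, std::vector<double>& x,
                       int o, int h1, int h2, double mO, double mH,
                       double dOH, double dHH) {
  double M = mO + 2.0 * mH;
  double rc = 0.5 * dHH;
  double t = std::sqrt(dOH * dOH - rc * rc);  // O to HH midpoint
  double ra = 2.0 * mH * t / M;               // COM to O
  double rb = t - ra;                         // COM to HH line

  const double* a0 = &ref[3 * o];
  const double* b0p = &ref[3 * h1];
  const double* c0p = &ref[3 * h2];
  double b0[3], c0[3];
  for (int c = 0; c < 3; ++c) { b0[c] = b0p[c] - a0[c]; c0[c] = c0p[c] - a0[c]; }

  double com[3];
  for (int c = 0; c < 3; ++c)
    com[c] = (mO * x[3 * o + c] + mH * x[3 * h1 + c] + mH * x[3 * h2 + c]) / M;
  double a1[3], b1[3], c1[3];
  for (int c = 0; c < 3; ++c) {
    a1[c] = x[3 * o + c] - com[c];
    b1[c] = x[3 * h1 + c] - com[c];
    c1[c] = x[3 * h2 + c] - com[c];
  }

  double n0[3], n1[3], n2[3];
  cross3(b0, c0, n0);
  double nn0 = norm3(n0);
  if (nn0 < 1e-12) return false;
  cross3(a1, n0, n1);
  double nn1 = norm3(n1);
  if (nn1 < 1e-12) return false;
  cross3(n0, n1, n2);
  double nn2 = norm3(n2);
  for (int c = 0; c < 3; ++c) { n0[c] /= nn0; n1[c] /= nn1; n2[c] /= nn2; }

  double b0d[3] = { dot3(n1, b0), dot3(n2, b0), dot3(n0, b0) };
  double c0d[3] = { dot3(n1, c0), dot3(n2, c0), dot3(n0, c0) };
  double a1d[3] = { dot3(n1, a1), dot3(n2, a1), dot3(n0, a1) };
  double b1d[3] = { dot3(n1, b1), dot3(n2, b1), dot3(n0, b1) };
  double c1d[3] = { dot3(n1, c1), dot3(n2, c1), dot3(n0, c1) };

  double sinphi = a1d[2] / ra;
  if (sinphi > 1.0) sinphi = 1.0;
  if (sinphi < -1.0) sinphi = -1.0;
  double cosphi = std::sqrt(1.0 - sinphi * sinphi);
  double sinpsi = (b1d[2] - c1d[2]) / (2.0 * rc * cosphi);
  if (sinpsi > 1.0) sinpsi = 1.0;
  if (sinpsi < -1.0) sinpsi = -1.0;
  double cospsi = std::sqrt(1.0 - sinpsi * sinpsi);

  double ya1d = ra * cosphi;
  double xb1d = -rc * cospsi;
  double yb1d = -rb * cosphi - rc * sinpsi * sinphi;
  double yc1d = -rb * cosphi + rc * sinpsi * sinphi;

  double alpha = xb1d * (b0d[0] - c0d[0]) + b0d[1] * yb1d + c0d[1] * yc1d;
  double beta = xb1d * (c0d[1] - b0d[1]) + b0d[0] * yb1d + c0d[0] * yc1d;
  double gamma = b0d[0] * b1d[1] - b1d[0] * b0d[1] + c0d[0] * c1d[1] - c1d[0] * c0d[1];
  double al2be2 = alpha * alpha + beta * beta;
  double under = al2be2 - gamma * gamma;
  if (under < 0.0 || al2be2 < 1e-16) return false;
  double sinth = (alpha * gamma - beta * std::sqrt(under)) / al2be2;
  if (sinth > 1.0 || sinth < -1.0) return false;
  double costh = std::sqrt(1.0 - sinth * sinth);

  double xa3d = -ya1d * sinth;
  double ya3d = ya1d * costh;
  double za3d = a1d[2];
  double xb3d = xb1d * costh - yb1d * sinth;
  double yb3d = xb1d * sinth + yb1d * costh;
  double zb3d = b1d[2];
  double xc3d = -xb1d * costh - yc1d * sinth;
  double yc3d = -xb1d * sinth + yc1d * costh;
  double zc3d = c1d[2];

  for (int c = 0; c < 3; ++c) {
    x[3 * o + c]  = com[c] + xa3d * n1[c] + ya3d * n2[c] + za3d * n0[c];
    x[3 * h1 + c] = com[c] + xb3d * n1[c] + yb3d * n2[c] + zb3d * n0[c];
    x[3 * h2 + c] = com[c] + xc3d * n1[c] + yc3d * n2[c] + zc3d * n0[c];
  }
  return true;
}

// apply SETTLE to all waters, with SHAKE fallback for degenerate geometries.
// returns number of fallbacks.
static int settle_all(const std::vector<double>& ref, std::vector<double>& x,
                      const IntegerMatrix& waters, double mO, double mH,
                      double dOH, double dHH,
                      const std::vector<double>& invmass) {
  int nfall = 0;
  for (int w = 0; w < waters.nrow(); ++w) {
    int o = waters(w, 0) - 1, h1 = waters(w, 1) - 1, h2 = waters(w, 2) - 1;
    if (!settle_one(ref, x, o, h1, h2, mO, mH, dOH, dHH)) {
      ++nfall;
      IntegerMatrix cons(3, 2);
      cons(0, 0) = o + 1; cons(0, 1) = h1 + 1;
      cons(1, 0) = o + 1; cons(1, 1) = h2 + 1;
      cons(2, 0) = h1 + 1; cons(2, 1) = h2 + 1;
      NumericVector d0 = NumericVector::create(dOH, dOH, dHH);
      if (shake_run(ref, x, cons, d0, invmass, 1e-8, 1000, 0) < 0)
        stop("constraint failure on water %d (SETTLE degenerate, SHAKE did not converge)", w + 1);
    }
  }
  return nfall;
}

// ---------------------------------------------------------------------------
// exported single-shot kernels

// [[Rcpp::export]]
List cpp_pair_list(NumericMatrix pos, NumericVector box, double cutoff,
                   IntegerVector groups, IntegerVector egrp,
                   NumericVector charge, IntegerVector type,
                   NumericMatrix c6tab, NumericMatrix c12tab,
                   IntegerMatrix excl) {
  int n = pos.nrow();
  std::vector<double> x(3 * n);
  for (int a = 0; a < n; ++a)
    for (int c = 0; c < 3; ++c) x[3 * a + c] = pos(a, c);
  std::vector<int> grp(n), eg(n), ty(n);
  int ngrp = 0; (void)ngrp;
  for (int a = 0; a < n; ++a) {
    grp[a] = groups[a] - 1;
    if (grp[a] + 1 > ngrp) ngrp = grp[a] + 1;
    eg[a] = egrp[a];
    ty[a] = type[a] - 1;
  }
  std::vector<double> q(charge.begin(), charge.end());
  ExclSet es = make_exclset(excl, n);
  Groups grps;
  grps.init(grp, n);
  PairList pl;
  build_group_pairlist(x, &box[0], cutoff, grps, eg, q, ty, c6tab, c12tab,
                       es, pl);
  int np = (int)pl.i.size();
  IntegerMatrix pairs(np, 2);
  IntegerMatrix shifts(np, 3);
  for (int gp = 0; gp < (int)pl.gp_i.size(); ++gp) {
    for (int k = pl.gp_start[gp]; k < pl.gp_start[gp + 1]; ++k) {
      pairs(k, 0) = pl.i[k] + 1;
      pairs(k, 1) = pl.j[k] + 1;
      shifts(k, 0) = pl.gp_mx[gp]; shifts(k, 1) = pl.gp_my[gp];
      shifts(k, 2) = pl.gp_mz[gp];
    }
  }
  return List::create(_["pairs"] = pairs, _["shifts"] = shifts);
}

// [[Rcpp::export]]
List cpp_energy_forces(NumericMatrix pos, NumericVector box,
                       NumericVector charge, IntegerVector type,
                       NumericMatrix c6tab, NumericMatrix c12tab,
                       IntegerVector groups, IntegerVector egrp,
                       IntegerMatrix excl, double cutoff, double rswitch,
                       double crf,
                       IntegerMatrix bonds, NumericVector bond_r0,
                       NumericVector bond_kb, IntegerMatrix angles,
                       NumericVector angle_th0, NumericVector angle_kth,
                       IntegerMatrix dihedrals, IntegerVector dih_mult,
                       NumericVector dih_phi0, NumericVector dih_kphi,
                       IntegerVector res_idx, NumericMatrix res_ref,
                       double res_k, bool use_bonds) {
  int n = pos.nrow();
  std::vector<double> x(3 * n), f(3 * n, 0.0);
  for (int a = 0; a < n; ++a)
    for (int c = 0; c < 3; ++c) x[3 * a + c] = pos(a, c);
  std::vector<int> grp(n), eg(n), ty(n);
  int ngrp = 0; (void)ngrp;
  for (int a = 0; a < n; ++a) {
    grp[a] = groups[a] - 1;
    if (grp[a] + 1 > ngrp) ngrp = grp[a] + 1;
    eg[a] = egrp[a];
    ty[a] = type[a] - 1;
  }
  std::vector<double> q(charge.begin(), charge.end());
  ExclSet es = make_exclset(excl, n);
  Groups grps;
  grps.init(grp, n);
  PairList pl;
  build_group_pairlist(x, &box[0], cutoff, grps, eg, q, ty, c6tab, c12tab,
                       es, pl);
  NbEnergies en;
  double virial = 0.0;
  nonbonded_eval(pl, x, &box[0], grps, cutoff, rswitch, crf, f, en, virial);
  excluded_rf_eval(excl, x, &box[0], cutoff, crf, q, eg, f, en, virial);
  double ebond = 0.0, eangle = 0.0, edih = 0.0, eres = 0.0;
  if (use_bonds && bonds.nrow() > 0)
    ebond = bonds_eval(bonds, bond_r0, bond_kb, x, f, virial);
  if (angles.nrow() > 0)
    eangle = angles_eval(angles, angle_th0, angle_kth, x, f, virial);
  if (dihedrals.nrow() > 0)
    edih = dihedrals_eval(dihedrals, dih_mult, dih_phi0, dih_kphi, x, f, virial);
  if (res_idx.size() > 0)
    eres = restraints_eval(res_idx, res_ref, res_k, x, f);
  NumericMatrix fout(n, 3);
  for (int a = 0; a < n; ++a)
    for (int c = 0; c < 3; ++c) fout(a, c) = f[3 * a + c];
  return List::create(
      _["e_vdw_pp"] = en.evdw[0], _["e_es_pp"] = en.ees[0],
      _["e_vdw_pw"] = en.evdw[1], _["e_es_pw"] = en.ees[1],
      _["e_vdw_ss"] = en.evdw[2], _["e_es_ss"] = en.ees[2],
      _["e_bond"] = ebond, _["e_angle"] = eangle, _["e_dihedral"] = edih,
      _["e_restraint"] = eres, _["forces"] = fout, _["virial"] = virial,
      _["n_pairs"] = (int)pl.i.size());
}

// [[Rcpp::export]]
List cpp_shake(NumericMatrix ref, NumericMatrix posnew, IntegerMatrix cons,
               NumericVector d0, NumericVector mass, double tol, int maxit) {
  int n = ref.nrow();
  std::vector<double> xr(3 * n), x(3 * n), invm(n);
  for (int a = 0; a < n; ++a) {
    invm[a] = 1.0 / mass[a];
    for (int c = 0; c < 3; ++c) {
      xr[3 * a + c] = ref(a, c);
      x[3 * a + c] = posnew(a, c);
    }
  }
  int bad = -2;
  int it = shake_run(xr, x, cons, d0, invm, tol, maxit, &bad);
  if (it < 0)
    stop("SHAKE did not converge in %d iterations (constraint %d)", maxit, bad + 1);
  NumericMatrix out(n, 3);
  for (int a = 0; a < n; ++a)
    for (int c = 0; c < 3; ++c) out(a, c) = x[3 * a + c];
  return List::create(_["positions"] = out, _["iterations"] = it);
}

// [[Rcpp::export]]
List cpp_settle(NumericMatrix ref, NumericMatrix posnew, IntegerMatrix waters,
                double mO, double mH, double dOH, double dHH,
                NumericVector mass) {
  int n = ref.nrow();
  std::vector<double> xr(3 * n), x(3 * n), invm(n);
  for (int a = 0; a < n; ++a) {
    invm[a] = 1.0 / mass[a];
    for (int c = 0; c < 3; ++c) {
      xr[3 * a + c] = ref(a, c);
      x[3 * a + c] = posnew(a, c);
    }
  }
  int nfall = settle_all(xr, x, waters, mO, mH, dOH, dHH, invm);
  NumericMatrix out(n, 3);
  for (int a = 0; a < n; ++a)
    for (int c = 0; c < 3; ++c) out(a, c) = x[3 * a + c];
  return List::create(_["positions"] = out, _["n_fallback"] = nfall);
}

// ---------------------------------------------------------------------------
// the MD step loop

// helper: solve 3x3 symmetric system I w = L (for angular momentum removal)
static bool solve3(const double I[3][3], const double L[3], double w[3]) {
  double a = I[0][0], b = I[0][1], c = I[0][2];
  double d = I[1][1], e = I[1][2], g = I[2][2];
  double det = a * (d * g - e * e) - b * (b * g - c * e) + c * (b * e - c * d);
  if (std::fabs(det) < 1e-18) return false;
  double inv[3][3];
  inv[0][0] = (d * g - e * e) / det;
  inv[0][1] = (c * e - b * g) / det;
  inv[0][2] = (b * e - c * d) / det;
  inv[1][1] = (a * g - c * c) / det;
  inv[1][2] = (b * c - a * e) / det;
  inv[2][2] = (a * d - b * b) / det;
  inv[1][0] = inv[0][1]; inv[2][0] = inv[0][2]; inv[2][1] = inv[1][2];
  for (int r = 0; r < 3; ++r)
    w[r] = inv[r][0] * L[0] + inv[r][1] * L[1] + inv[r][2] * L[2];
  return true;
}

// remove net linear (and optionally angular) momentum of a set of atoms
static void remove_motion(std::vector<double>& v, const std::vector<double>& x,
                          const std::vector<double>& mass,
                          const std::vector<int>& idx, bool angular) {
  double M = 0.0, P[3] = {0, 0, 0}, com[3] = {0, 0, 0};
  for (size_t k = 0; k < idx.size(); ++k) {
    int a = idx[k];
    M += mass[a];
    for (int c = 0; c < 3; ++c) {
      P[c] += mass[a] * v[3 * a + c];
      com[c] += mass[a] * x[3 * a + c];
    }
  }
  if (M <= 0.0) return;
  for (int c = 0; c < 3; ++c) com[c] /= M;
  double vcom[3] = { P[0] / M, P[1] / M, P[2] / M };
  for (size_t k = 0; k < idx.size(); ++k) {
    int a = idx[k];
    for (int c = 0; c < 3; ++c) v[3 * a + c] -= vcom[c];
  }
  if (!angular) return;
  double L[3] = {0, 0, 0}, I[3][3] = {{0, 0, 0}, {0, 0, 0}, {0, 0, 0}};
  for (size_t k = 0; k < idx.size(); ++k) {
    int a = idx[k];
    double r[3] = { x[3 * a] - com[0], x[3 * a + 1] - com[1], x[3 * a + 2] - com[2] };
    double vv[3] = { v[3 * a], v[3 * a + 1], v[3 * a + 2] };
    double lv[3];
    cross3(r, vv, lv);
    for (int c = 0; c < 3; ++c) L[c] += mass[a] * lv[c];
    double r2 = dot3(r, r);
    for (int c1 = 0; c1 < 3; ++c1)
      for (int c2 = 0; c2 < 3; ++c2)
        I[c1][c2] += mass[a] * ((c1 == c2 ? r2 : 0.0) - r[c1] * r[c2]);
  }
  double w[3];
  if (!solve3(I, L, w)) return;
  for (size_t k = 0; k < idx.size(); ++k) {
    int a = idx[k];
    double r[3] = { x[3 * a] - com[0], x[3 * a + 1] - com[1], x[3 * a + 2] - com[2] };
    double wr[3];
    cross3(w, r, wr);
    for (int c = 0; c < 3; ++c) v[3 * a + c] -= wr[c];
  }
}

// [[Rcpp::export]]
List cpp_run_md(NumericMatrix pos, NumericMatrix vel, NumericVector box_in,
                NumericVector mass, NumericVector charge, IntegerVector type,
                NumericMatrix c6tab, NumericMatrix c12tab,
                IntegerVector groups, IntegerVector egrp, IntegerMatrix excl,
                IntegerMatrix waters, NumericVector water_geom,  // dOH, dHH, mO, mH
                IntegerMatrix scons, NumericVector scons_d0,     // solute constraints
                IntegerMatrix angles, NumericVector angle_th0, NumericVector angle_kth,
                IntegerMatrix dihedrals, IntegerVector dih_mult,
                NumericVector dih_phi0, NumericVector dih_kphi,
                IntegerVector res_idx, NumericMatrix res_ref, double res_k,
                IntegerVector solute_idx, IntegerVector ion_idx,
                List params) {
  int n = pos.nrow();
  std::vector<double> x(3 * n), v(3 * n), m(n), invm(n), q(n);
  for (int a = 0; a < n; ++a) {
    m[a] = mass[a];
    invm[a] = 1.0 / mass[a];
    q[a] = charge[a];
    for (int c = 0; c < 3; ++c) {
      x[3 * a + c] = pos(a, c);
      v[3 * a + c] = vel(a, c);
    }
  }
  double box[3] = { box_in[0], box_in[1], box_in[2] };

  int nsteps = as<int>(params["nsteps"]);
  double dt = as<double>(params["dt"]);
  double cutoff = as<double>(params["cutoff"]);
  double rswitch = as<double>(params["rswitch"]);
  double crf = as<double>(params["crf"]);
  double skin = as<double>(params["skin"]);
  int nstlist = as<int>(params["nstlist"]);
  double shake_tol = as<double>(params["shake_tol"]);
  int shake_maxit = as<int>(params["shake_maxit"]);
  NumericVector bath_T = params["bath_T"];      // solute, trans, rot (<=0: uncoupled)
  NumericVector bath_tau = params["bath_tau"];
  double dof_solute = as<double>(params["dof_solute"]);
  double dof_trans = as<double>(params["dof_trans"]);   // includes ion dof
  double dof_rot = as<double>(params["dof_rot"]);
  int com_interval = as<int>(params["com_interval"]);   // 0: never
  bool rototrans = as<bool>(params["rototrans"]);
  bool barostat = as<bool>(params["barostat"]);
  double p_target = as<double>(params["p_target"]);
  double p_tau = as<double>(params["p_tau"]);
  double p_kappa = as<double>(params["p_kappa"]);
  int sample_every = as<int>(params["sample_every"]);
  int frame_every = as<int>(params["frame_every"]);     // 0: no frames
  int step_offset = as<int>(params["step_offset"]);     // global step phase
  double t0 = as<double>(params["t0"]);
  double lambda_max = as<double>(params["lambda_max"]);

  std::vector<int> grp(n), eg(n), ty(n);
  int ngrp = 0; (void)ngrp;
  for (int a = 0; a < n; ++a) {
    grp[a] = groups[a] - 1;
    if (grp[a] + 1 > ngrp) ngrp = grp[a] + 1;
    eg[a] = egrp[a];
    ty[a] = type[a] - 1;
  }
  ExclSet es = make_exclset(excl, n);

  int nw = waters.nrow();
  double dOH = water_geom[0], dHH = water_geom[1];
  double mO = water_geom[2], mH = water_geom[3];
  std::vector<int> sol(solute_idx.size()), ions(ion_idx.size());
  for (int k = 0; k < solute_idx.size(); ++k) sol[k] = solute_idx[k] - 1;
  for (int k = 0; k < ion_idx.size(); ++k) ions[k] = ion_idx[k] - 1;
  std::vector<int> allidx(n);
  for (int a = 0; a < n; ++a) allidx[a] = a;

  Groups grps;
  grps.init(grp, n);
  PairList pl;
  std::vector<double> f(3 * n, 0.0);

  int nsamp = (sample_every > 0) ? (nsteps / sample_every) : 0;
  NumericMatrix temp_series(nsamp, 4);     // time, T_solute, T_trans, T_rot
  NumericMatrix en_series(nsamp, 13);
  int nframes = (frame_every > 0) ? (nsteps / frame_every) : 0;
  List frames(nframes);
  NumericVector frame_times(nframes);
  int isamp = 0, iframe = 0, n_lambda_cap = 0, n_settle_fallback = 0;

  std::vector<double> xun(3 * n);  // unconstrained positions
  NbEnergies en;

  for (int step = 0; step < nsteps; ++step) {
    if (step % 2048 == 0) Rcpp::checkUserInterrupt();
    // 1. neighbour list
    if (step % nstlist == 0) {
      build_group_pairlist(x, box, cutoff + skin, grps, eg, q, ty,
                           c6tab, c12tab, es, pl);
    }
    // 2. forces
    std::fill(f.begin(), f.end(), 0.0);
    en = NbEnergies();
    double virial = 0.0;
    nonbonded_eval(pl, x, box, grps, cutoff, rswitch, crf, f, en, virial);
    excluded_rf_eval(excl, x, box, cutoff, crf, q, eg, f, en, virial);
    double eangle = 0.0, edih = 0.0, eres = 0.0;
    if (angles.nrow() > 0)
      eangle = angles_eval(angles, angle_th0, angle_kth, x, f, virial);
    if (dihedrals.nrow() > 0)
      edih = dihedrals_eval(dihedrals, dih_mult, dih_phi0, dih_kphi, x, f, virial);
    if (res_idx.size() > 0 && res_k > 0.0)
      eres = restraints_eval(res_idx, res_ref, res_k, x, f);

    // 3. leapfrog
    for (int a = 0; a < n; ++a)
      for (int c = 0; c < 3; ++c) {
        double fa = f[3 * a + c];
        if (!std::isfinite(fa))
          stop("non-finite force on atom %d at step %d", a + 1, step + 1);
        v[3 * a + c] += fa * invm[a] * dt;
        xun[3 * a + c] = x[3 * a + c] + v[3 * a + c] * dt;
      }
    std::vector<double> xold(x);
    std::vector<double> xc(xun);
    // 4. constraints
    double cvir = 0.0;
    if (nw > 0)
      n_settle_fallback += settle_all(x, xc, waters, mO, mH, dOH, dHH, invm);
    if (scons.nrow() > 0) {
      int bad = -2;
      if (shake_run(x, xc, scons, scons_d0, invm, shake_tol, shake_maxit, &bad) < 0)
        stop("SHAKE failure at step %d (constraint %d)", step + 1, bad + 1);
    }
    // constraint virial: f_c . (x - molecular com), needed for the
    // atomic-virial pressure of rigid molecules
    {
      for (int w = 0; w < nw; ++w) {
        int ww[3] = { waters(w, 0) - 1, waters(w, 1) - 1, waters(w, 2) - 1 };
        double com[3] = {0, 0, 0}, Mw = mO + 2 * mH;
        for (int s = 0; s < 3; ++s) {
          double ms = (s == 0) ? mO : mH;
          for (int c = 0; c < 3; ++c) com[c] += ms * xc[3 * ww[s] + c];
        }
        for (int c = 0; c < 3; ++c) com[c] /= Mw;
        for (int s = 0; s < 3; ++s) {
          int a = ww[s];
          for (int c = 0; c < 3; ++c) {
            double fc = (xc[3 * a + c] - xun[3 * a + c]) * m[a] / (dt * dt);
            cvir += fc * (xc[3 * a + c] - com[c]);
          }
        }
      }
      if (scons.nrow() > 0 && sol.size() > 0) {
        double com[3] = {0, 0, 0}, Ms = 0.0;
        for (size_t k = 0; k < sol.size(); ++k) {
          Ms += m[sol[k]];
          for (int c = 0; c < 3; ++c) com[c] += m[sol[k]] * xc[3 * sol[k] + c];
        }
        for (int c = 0; c < 3; ++c) com[c] /= Ms;
        for (size_t k = 0; k < sol.size(); ++k) {
          int a = sol[k];
          for (int c = 0; c < 3; ++c) {
            double fc = (xc[3 * a + c] - xun[3 * a + c]) * m[a] / (dt * dt);
            cvir += fc * (xc[3 * a + c] - com[c]);
          }
        }
      }
    }
    x = xc;
    // velocities consistent with constrained positions
    for (int a = 0; a < n; ++a)
      for (int c = 0; c < 3; ++c)
        v[3 * a + c] = (x[3 * a + c] - xold[3 * a + c]) / dt;

    // 5. global motion removal
    if (rototrans && sol.size() >= 2)
      remove_motion(v, x, m, sol, true);
    if (com_interval > 0 && (step_offset + step + 1) % com_interval == 0)
      remove_motion(v, x, m, allidx, false);

    // 6. kinetic partition
    double ke_solute = 0.0, ke_trans = 0.0, ke_rot = 0.0, ke_ion = 0.0;
    for (size_t k = 0; k < sol.size(); ++k) {
      int a = sol[k];
      ke_solute += 0.5 * m[a] * (v[3 * a] * v[3 * a] + v[3 * a + 1] * v[3 * a + 1] +
                                 v[3 * a + 2] * v[3 * a + 2]);
    }
    for (size_t k = 0; k < ions.size(); ++k) {
      int a = ions[k];
      ke_ion += 0.5 * m[a] * (v[3 * a] * v[3 * a] + v[3 * a + 1] * v[3 * a + 1] +
                              v[3 * a + 2] * v[3 * a + 2]);
    }
    double Mw = mO + 2.0 * mH;
    std::vector<double> vcomw(3 * nw);
    for (int w = 0; w < nw; ++w) {
      int o = waters(w, 0) - 1, h1 = waters(w, 1) - 1, h2 = waters(w, 2) - 1;
      double ketot = 0.0;
      for (int c = 0; c < 3; ++c) {
        double pc = mO * v[3 * o + c] + mH * v[3 * h1 + c] + mH * v[3 * h2 + c];
        vcomw[3 * w + c] = pc / Mw;
        ke_trans += 0.5 * pc * pc / Mw;
      }
      ketot += 0.5 * mO * dot3(&v[3 * o], &v[3 * o]);
      ketot += 0.5 * mH * dot3(&v[3 * h1], &v[3 * h1]);
      ketot += 0.5 * mH * dot3(&v[3 * h2], &v[3 * h2]);
      double kec = 0.5 * Mw * dot3(&vcomw[3 * w], &vcomw[3 * w]);
      ke_rot += ketot - kec;
    }
    double T_solute = (dof_solute > 0) ? 2.0 * ke_solute / (dof_solute * KB) : 0.0;
    double T_trans = (dof_trans > 0) ? 2.0 * (ke_trans + ke_ion) / (dof_trans * KB) : 0.0;
    double T_rot = (dof_rot > 0) ? 2.0 * ke_rot / (dof_rot * KB) : 0.0;

    // 7. weak-coupling thermostats
    double lam[3] = { 1.0, 1.0, 1.0 };
    double Tinst[3] = { T_solute, T_trans, T_rot };
    for (int b = 0; b < 3; ++b) {
      if (bath_T[b] <= 0.0) continue;
      if (Tinst[b] <= 1e-12) {
        lam[b] = lambda_max;
        ++n_lambda_cap;
        continue;
      }
      double l2 = 1.0 + (dt / bath_tau[b]) * (bath_T[b] / Tinst[b] - 1.0);
      double l = (l2 > 0.0) ? std::sqrt(l2) : 0.0;
      if (l > lambda_max) { l = lambda_max; ++n_lambda_cap; }
      lam[b] = l;
    }
    if (lam[0] != 1.0)
      for (size_t k = 0; k < sol.size(); ++k) {
        int a = sol[k];
        for (int c = 0; c < 3; ++c) v[3 * a + c] *= lam[0];
      }
    if (lam[1] != 1.0)
      for (size_t k = 0; k < ions.size(); ++k) {
        int a = ions[k];
        for (int c = 0; c < 3; ++c) v[3 * a + c] *= lam[1];
      }
    if (nw > 0 && (lam[1] != 1.0 || lam[2] != 1.0)) {
      for (int w = 0; w < nw; ++w) {
        int ww[3] = { waters(w, 0) - 1, waters(w, 1) - 1, waters(w, 2) - 1 };
        for (int s = 0; s < 3; ++s) {
          int a = ww[s];
          for (int c = 0; c < 3; ++c) {
            double vc = vcomw[3 * w + c];
            v[3 * a + c] = lam[1] * vc + lam[2] * (v[3 * a + c] - vc);
          }
        }
      }
    }

    // 8. pressure coupling (isotropic Berendsen, molecule-COM scaling)
    double P_inst = 0.0;
    double ke_all = ke_solute + ke_ion + ke_trans + ke_rot;
    double volume = box[0] * box[1] * box[2];
    P_inst = (2.0 * ke_all + virial + cvir) / (3.0 * volume) * P_UNIT;
    if (barostat) {
      double mu3 = 1.0 - (dt / p_tau) * p_kappa * (p_target - P_inst);
      double mu = std::cbrt(mu3);
      if (mu < 0.95) mu = 0.95;
      if (mu > 1.05) mu = 1.05;
      for (int c = 0; c < 3; ++c) box[c] *= mu;
      // scale molecule COMs, rigid shift of members
      for (int w = 0; w < nw; ++w) {
        int ww[3] = { waters(w, 0) - 1, waters(w, 1) - 1, waters(w, 2) - 1 };
        double com[3] = {0, 0, 0};
        for (int s = 0; s < 3; ++s) {
          double ms = (s == 0) ? mO : mH;
          for (int c = 0; c < 3; ++c) com[c] += ms * x[3 * ww[s] + c] / Mw;
        }
        for (int s = 0; s < 3; ++s)
          for (int c = 0; c < 3; ++c)
            x[3 * ww[s] + c] += (mu - 1.0) * com[c];
      }
      for (size_t k = 0; k < ions.size(); ++k)
        for (int c = 0; c < 3; ++c) x[3 * ions[k] + c] *= mu;
      if (sol.size() > 0) {
        double com[3] = {0, 0, 0}, Ms = 0.0;
        for (size_t k = 0; k < sol.size(); ++k) {
          Ms += m[sol[k]];
          for (int c = 0; c < 3; ++c) com[c] += m[sol[k]] * x[3 * sol[k] + c];
        }
        for (int c = 0; c < 3; ++c) com[c] /= Ms;
        for (size_t k = 0; k < sol.size(); ++k)
          for (int c = 0; c < 3; ++c)
            x[3 * sol[k] + c] += (mu - 1.0) * com[c];
      }
    }

    // 9. sampling
    if (sample_every > 0 && (step + 1) % sample_every == 0 && isamp < nsamp) {
      double t = t0 + (step + 1) * dt;
      temp_series(isamp, 0) = t;
      temp_series(isamp, 1) = T_solute;
      temp_series(isamp, 2) = T_trans;
      temp_series(isamp, 3) = T_rot;
      en_series(isamp, 0) = t;
      en_series(isamp, 1) = en.evdw[0];
      en_series(isamp, 2) = en.ees[0];
      en_series(isamp, 3) = en.evdw[1];
      en_series(isamp, 4) = en.ees[1];
      en_series(isamp, 5) = en.evdw[2];
      en_series(isamp, 6) = en.ees[2];
      en_series(isamp, 7) = eangle + edih;
      en_series(isamp, 8) = eres;
      en_series(isamp, 9) = ke_all;
      en_series(isamp, 10) = P_inst;
      en_series(isamp, 11) = volume;
      en_series(isamp, 12) = en.evdw[0] + en.ees[0] + en.evdw[1] + en.ees[1] +
                             en.evdw[2] + en.ees[2] + eangle + edih;
      ++isamp;
    }
    if (frame_every > 0 && (step + 1) % frame_every == 0 && iframe < nframes) {
      NumericMatrix fr(n, 3);
      for (int a = 0; a < n; ++a)
        for (int c = 0; c < 3; ++c) fr(a, c) = x[3 * a + c];
      frames[iframe] = fr;
      frame_times[iframe] = t0 + (step + 1) * dt;
      ++iframe;
    }
  }

  NumericMatrix pout(n, 3), vout(n, 3);
  for (int a = 0; a < n; ++a)
    for (int c = 0; c < 3; ++c) {
      pout(a, c) = x[3 * a + c];
      vout(a, c) = v[3 * a + c];
    }

  return List::create(
      _["positions"] = pout, _["velocities"] = vout,
      _["box"] = NumericVector::create(box[0], box[1], box[2]),
      _["temp_series"] = temp_series, _["energy_series"] = en_series,
      _["frames"] = frames, _["frame_times"] = frame_times,
      _["n_lambda_cap"] = n_lambda_cap,
      _["n_settle_fallback"] = n_settle_fallback);
}
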