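// Coarse-grained force/energy kernels and the MD integrator.
// Units: nm, ps, amu, kJ/mol, elementary charge (GROMACS-consistent, so
// 1 kJ mol^-1 nm^-1 / amu = 1 nm ps^-2).

#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <algorithm>
using namespace Rcpp;

static const double KB = 0.0083145;        // kJ mol^-1 K^-1
static const double KE_COUL = 138.935;     // kJ mol^-1 nm e^-2
static const double R_FLOOR = 0.01;        // nm, overlap error threshold

struct Vec3 { double x, y, z; };

struct Engine {
  int n;
  std::vector<int> type;
  std::vector<double> mass, charge;
  NumericMatrix eps_t, c_t;
  // bonded terms
  std::vector<int> bi, bj; std::vector<double> bK, bL;
  std::vector<int> ai, aj, ak, atype;
  std::vector<int> ga_off; std::vector<double> ga_a, ga_b, ga_c;
  std::vector<int> di, dj, dk, dl, dtype;
  std::vector<int> gt_off; std::vector<double> gt_a, gt_b, gt_c;
  // exclusions (CSR, sorted)
  std::vector<int> excl_ptr, excl_idx;
  double er, cutoff;
  bool pbc; double box[3];

  // pair list state
  double skin;
  std::vector<std::pair<int,int> > pairs;
  std::vector<double> ref_pos;

  void init(const List &inp, const NumericVector &boxv) {
    n = as<int>(inp["n"]);
    type = as<std::vector<int> >(inp["type"]);
    mass = as<std::vector<double> >(inp["mass"]);
    charge = as<std::vector<double> >(inp["charge"]);
    eps_t = as<NumericMatrix>(inp["eps_table"]);
    c_t = as<NumericMatrix>(inp["c_table"]);
    bi = as<std::vector<int> >(inp["bond_i"]);
    bj = as<std::vector<int> >(inp["bond_j"]);
    bK = as<std::vector<double> >(inp["bond_K"]);
    bL = as<std::vector<double> >(inp["bond_L"]);
    ai = as<std::vector<int> >(inp["ang_i"]);
    aj = as<std::vector<int> >(inp["ang_j"]);
    ak = as<std::vector<int> >(inp["ang_k"]);
    atype = as<std::vector<int> >(inp["ang_type"]);
    ga_off = as<std::vector<int> >(inp["ga_off"]);
    ga_a = as<std::vector<double> >(inp["ga_a"]);
    ga_b = as<std::vector<double> >(inp["ga_b"]);
    ga_c = as<std::vector<double> >(inp["ga_c"]);
    di = as<std::vector<int> >(inp["dih_i"]);
    dj = as<std::vector<int> >(inp["dih_j"]);
    dk = as<std::vector<int> >(inp["dih_k"]);
    dl = as<std::vector<int> >(inp["dih_l"]);
    dtype = as<std::vector<int> >(inp["dih_type"]);
    gt_off = as<std::vector<int> >(inp["gt_off"]);
    gt_a = as<std::vector<double> >(inp["gt_a"]);
    gt_b = as<std::vector<double> >(inp["gt_b"]);
    gt_c = as<std::vector<double> >(inp["gt_c"]);
    excl_ptr = as<std::vector<int> >(inp["excl_ptr"]);
    excl_idx = as<std::vector<int> >(inp["excl_idx"]);
    er = as<double>(inp["er"]);
    cutoff = as<double>(inp["cutoff"]);
    pbc = boxv.size() == 3;
    if (pbc) { box[0] = boxv[0]; box[1] = boxv[1]; box[2] = boxv[2]; }
    skin = 0.3;
    ref_pos.assign(3 * n, 1e30);
  }

  inline void min_image(double &dx, double &dy, double &dz) const {
    if (!pbc) return;
    dx -= box[0] * std::round(dx / box[0]);
    dy -= box[1] * std::round(dy / box[1]);
    dz -= box[2] * std::round(dz / box[2]);
  }

  inline bool excluded(int i, int j) const {
    int lo = excl_ptr[i], hi = excl_ptr[i + 1];
    return std::binary_search(excl_idx.begin() + lo,
                              excl_idx.begin() + hi, j);
  }

  void build_pairs(const std::vector<double> &pos) {
    pairs.clear();
    double rl = cutoff + skin, rl2 = rl * rl;
    bool cells_ok = pbc;
    int nc[3] = {1, 1, 1};
    if (pbc) {
      for (int d = 0; d < 3; ++d) {
        nc[d] = std::max(1, (int)std::floor(box[d] / rl));
        if (nc[d] < 3) cells_ok = false;
      }
    }
    if (cells_ok) {
      int ncell = nc[0] * nc[1] * nc[2];
      std::vector<std::vector<int> > bins(ncell);
      std::vector<int> ci(n), cj(n), ck(n);
      for (int p = 0; p < n; ++p) {
        double w[3] = {pos[3 * p], pos[3 * p + 1], pos[3 * p + 2]};
        int idx[3];
        for (int d = 0; d < 3; ++d) {
          double f = w[d] / box[d];
          f -= std::floor(f);
          idx[d] = std::min(nc[d] - 1, (int)std::floor(f * nc[d]));
        }
        ci[p] = idx[0]; cj[p] = idx[1]; ck[p] = idx[2];
        bins[(idx[2] * nc[1] + idx[1]) * nc[0] + idx[0]].push_back(p);
      }
      for (int p = 0; p < n; ++p) {
        for (int dz = -1; dz <= 1; ++dz)
          for (int dy = -1; dy <= 1; ++dy)
            for (int dx = -1; dx <= 1; ++dx) {
              int cx = (ci[p] + dx + nc[0]) % nc[0];
              int cy = (cj[p] + dy + nc[1]) % nc[1];
              int cz = (ck[p] + dz + nc[2]) % nc[2];
              const std::vector<int> &bin =
                bins[(cz * nc[1] + cy) * nc[0] + cx];
              for (size_t t = 0; t < bin.size(); ++t) {
                int q = bin[t];
                if (q <= p) continue;
                double ddx = pos[3 * q] - pos[3 * p];
                double ddy = pos[3 * q + 1] - pos[3 * p + 1];
                double ddz = pos[3 * q + 2] - pos[3 * p + 2];
                min_image(ddx, ddy, ddz);
                if (ddx * ddx + ddy * ddy + ddz * ddz < rl2 &&
                    !excluded(p, q))
                  pairs.push_back(std::make_pair(p, q));
              }
            }
      }
      // neighbouring cells can coincide when nc==3 with wrap; dedupe
      std::sort(pairs.begin(), pairs.end());
      pairs.erase(std::unique(pairs.begin(), pairs.end()), pairs.end());
    } else {
      for (int p = 0; p < n; ++p)
        for (int q = p + 1; q < n; ++q) {
          double ddx = pos[3 * q] - pos[3 * p];
          double ddy = pos[3 * q + 1] - pos[3 * p + 1];
          double ddz = pos[3 * q + 2] - pos[3 * p + 2];
          min_image(ddx, ddy, ddz);
          if (ddx * ddx + ddy * ddy + ddz * ddz < rl2 && !excluded(p, q))
            pairs.push_back(std::make_pair(p, q));
        }
    }
    ref_pos = pos;
  }

  bool need_rebuild(const std::vector<double> &pos) const {
    double lim2 = 0.25 * skin * skin;
    for (int p = 0; p < 3 * n; p += 3) {
      double dx = pos[p] - ref_pos[p];
      double dy = pos[p + 1] - ref_pos[p + 1];
      double dz = pos[p + 2] - ref_pos[p + 2];
      if (dx * dx + dy * dy + dz * dz > lim2) return true;
    }
    return false;
  }

  inline double gsum(double x, const std::vector<int> &off,
                     const std::vector<double> &a,
                     const std::vector<double> &b,
                     const std::vector<double> &c,
                     int t, bool wrap, double &dudx) const {
    double u = 0; dudx = 0;
    for (int k = off[t]; k < off[t + 1]; ++k) {
      double dx = x - b[k];
      if (wrap) {
        dx -= 2.0 * M_PI * std::floor((dx + M_PI) / (2.0 * M_PI));
        if (dx <= -M_PI) dx = M_PI;   // minimum image onto (-pi, pi]
      }
      double e = a[k] * std::exp(-(dx * dx) / (c[k] * c[k]));
      u += e;
      dudx += -2.0 * dx / (c[k] * c[k]) * e;
    }
    return u;
  }

  // evaluate energies and forces; returns false (with *bad = index) on
  // overlapping beads
  void eval(const std::vector<double> &pos, std::vector<double> &frc,
            double U[5]) {
    if (need_rebuild(pos)) build_pairs(pos);
    std::fill(frc.begin(), frc.end(), 0.0);
    U[0] = U[1] = U[2] = U[3] = U[4] = 0.0;

    // bonds
    for (size_t t = 0; t < bi.size(); ++t) {
      int i = bi[t], j = bj[t];
      double dx = pos[3*j] - pos[3*i], dy = pos[3*j+1] - pos[3*i+1],
             dz = pos[3*j+2] - pos[3*i+2];
      min_image(dx, dy, dz);
      double r = std::sqrt(dx*dx + dy*dy + dz*dz);
      double dr = r - bL[t];
      U[0] += 0.5 * bK[t] * dr * dr;
      double f = -bK[t] * dr / r;   // along i->j acting on j
      frc[3*j] += f * dx;   frc[3*j+1] += f * dy;   frc[3*j+2] += f * dz;
      frc[3*i] -= f * dx;   frc[3*i+1] -= f * dy;   frc[3*i+2] -= f * dz;
    }

    // angles
    for (size_t t = 0; t < ai.size(); ++t) {
      int i = ai[t], j = aj[t], k = ak[t];
      double ux = pos[3*i] - pos[3*j], uy = pos[3*i+1] - pos[3*j+1],
             uz = pos[3*i+2] - pos[3*j+2];
      double vx = pos[3*k] - pos[3*j], vy = pos[3*k+1] - pos[3*j+1],
             vz = pos[3*k+2] - pos[3*j+2];
      min_image(ux, uy, uz); min_image(vx, vy, vz);
      double nu = std::sqrt(ux*ux + uy*uy + uz*uz);
      double nv = std::sqrt(vx*vx + vy*vy + vz*vz);
      double ct = (ux*vx + uy*vy + uz*vz) / (nu * nv);
      ct = std::max(-1.0, std::min(1.0, ct));
      double theta = std::acos(ct);
      double st = std::sqrt(std::max(1e-12, 1.0 - ct * ct));
      double dudt;
      U[1] += gsum(theta, ga_off, ga_a, ga_b, ga_c, atype[t], false, dudt);
      double coef = dudt / st;
      double fix = coef * (vx / nv - ct * ux / nu) / nu;
      double fiy = coef * (vy / nv - ct * uy / nu) / nu;
      double fiz = coef * (vz / nv - ct * uz / nu) / nu;
      double fkx = coef * (ux / nu - ct * vx / nv) / nv;
      double fky = coef * (uy / nu - ct * vy / nv) / nv;
      double fkz = coef * (uz / nu - ct * vz / nv) / nv;
      frc[3*i] += fix; frc[3*i+1] += fiy; frc[3*i+2] += fiz;
      frc[3*k] += fkx; frc[3*k+1] += fky; frc[3*k+2] += fkz;
      frc[3*j] -= fix + fkx; frc[3*j+1] -= fiy + fky;
      frc[3*j+2] -= fiz + fkz;
    }

    // dihedrals
    for (size_t t = 0; t < di.size(); ++t) {
      int i = di[t], j = dj[t], k = dk[t], l = dl[t];
      double b1x = pos[3*j]-pos[3*i], b1y = pos[3*j+1]-pos[3*i+1],
             b1z = pos[3*j+2]-pos[3*i+2];
      double b2x = pos[3*k]-pos[3*j], b2y = pos[3*k+1]-pos[3*j+1],
             b2z = pos[3*k+2]-pos[3*j+2];
      double b3x = pos[3*l]-pos[3*k], b3y = pos[3*l+1]-pos[3*k+1],
             b3z = pos[3*l+2]-pos[3*k+2];
      min_image(b1x, b1y, b1z); min_image(b2x, b2y, b2z);
      min_image(b3x, b3y, b3z);
      double mx = b1y*b2z - b1z*b2y, my = b1z*b2x - b1x*b2z,
             mz = b1x*b2y - b1y*b2x;
      double nx = b2y*b3z - b2z*b3y, ny = b2z*b3x - b2x*b3z,
             nz = b2x*b3y - b2y*b3x;
      double nb2 = std::sqrt(b2x*b2x + b2y*b2y + b2z*b2z);
      double cxx = my*nz - mz*ny, cxy = mz*nx - mx*nz,
             cxz = mx*ny - my*nx;
      double phi = std::atan2((cxx*b2x + cxy*b2y + cxz*b2z) / nb2,
                              mx*nx + my*ny + mz*nz);
      double dudphi;
      U[2] += gsum(phi, gt_off, gt_a, gt_b, gt_c, dtype[t], true, dudphi);
      double m2 = mx*mx + my*my + mz*mz;
      double n2 = nx*nx + ny*ny + nz*nz;
      if (m2 < 1e-12 || n2 < 1e-12) continue;  // collinear; no torque
      // dphi/dri = -(|b2|/|m|^2) m, dphi/drl = +(|b2|/|n|^2) n, with
      // b1 = rj - ri; interior gradients follow from translation and
      // rotation invariance.
      double fi = dudphi * nb2 / m2;
      double flc = -dudphi * nb2 / n2;
      double Fix = fi * mx, Fiy = fi * my, Fiz = fi * mz;
      double Flx = flc * nx, Fly = flc * ny, Flz = flc * nz;
      double tv = (b1x*b2x + b1y*b2y + b1z*b2z) / (nb2 * nb2);
      double sv = (b3x*b2x + b3y*b2y + b3z*b2z) / (nb2 * nb2);
      double Fjx = -(1 + tv) * Fix + sv * Flx;
      double Fjy = -(1 + tv) * Fiy + sv * Fly;
      double Fjz = -(1 + tv) * Fiz + sv * Flz;
      double Fkx = tv * Fix - (1 + sv) * Flx;
      double Fky = tv * Fiy - (1 + sv) * Fly;
      double Fkz = tv * Fiz - (1 + sv) * Flz;
      frc[3*i] += Fix; frc[3*i+1] += Fiy; frc[3*i+2] += Fiz;
      frc[3*j] += Fjx; frc[3*j+1] += Fjy; frc[3*j+2] += Fjz;
      frc[3*k] += Fkx; frc[3*k+1] += Fky; frc[3*k+2] += Fkz;
      frc[3*l] += Flx; frc[3*l+1] += Fly; frc[3*l+2] += Flz;
    }

    // non-bonded (shifted LJ + Coulomb within cutoff)
    double rc = cutoff, rc2 = rc * rc;
    for (size_t t = 0; t < pairs.size(); ++t) {
      int i = pairs[t].first, j = pairs[t].second;
      double dx = pos[3*j] - pos[3*i], dy = pos[3*j+1] - pos[3*i+1],
             dz = pos[3*j+2] - pos[3*i+2];
      min_image(dx, dy, dz);
      double r2 = dx*dx + dy*dy + dz*dz;
      if (r2 >= rc2) continue;
      double r = std::sqrt(r2);
      if (r < R_FLOOR)
        stop("bead overlap: pair distance below 0.01 nm");
      double eps = eps_t(type[i], type[j]);
      double cc = c_t(type[i], type[j]);
      double s6 = std::pow(cc / r, 6), s12 = s6 * s6;
      double sc6 = std::pow(cc / rc, 6), sc12 = sc6 * sc6;
      U[3] += 4.0 * eps * (s12 - s6) - 4.0 * eps * (sc12 - sc6);
      double fr = 4.0 * eps * (12.0 * s12 - 6.0 * s6) / r2; // (1/r dU/dr)*-1
      double qq = charge[i] * charge[j];
      if (qq != 0.0) {
        U[4] += KE_COUL * qq / er * (1.0 / r - 1.0 / rc);
        fr += KE_COUL * qq / (er * r2 * r);
      }
      frc[3*j] += fr * dx; frc[3*j+1] += fr * dy; frc[3*j+2] += fr * dz;
      frc[3*i] -= fr * dx; frc[3*i+1] -= fr * dy; frc[3*i+2] -= fr * dz;
    }
  }
};

static std::vector<double> mat_to_vec(const NumericMatrix &m) {
  std::vector<double> v(3 * m.nrow());
  for (int i = 0; i < m.nrow(); ++i) {
    v[3*i] = m(i, 0); v[3*i+1] = m(i, 1); v[3*i+2] = m(i, 2);
  }
  return v;
}

static NumericMatrix vec_to_mat(const std::vector<double> &v) {
  int n = v.size() / 3;
  NumericMatrix m(n, 3);
  for (int i = 0; i < n; ++i) {
    m(i, 0) = v[3*i]; m(i, 1) = v[3*i+1]; m(i, 2) = v[3*i+2];
  }
  return m;
}

// [[Rcpp::export]]
List cg_engine_eval(NumericMatrix pos, List inp, NumericVector box) {
  Engine eng;
  eng.init(inp, box);
  std::vector<double> p = mat_to_vec(pos), f(p.size());
  double U[5];
  eng.eval(p, f, U);
  return List::create(
    _["U_bond"] = U[0], _["U_angle"] = U[1], _["U_torsion"] = U[2],
    _["U_vdw"] = U[3], _["U_elec"] = U[4],
    _["U_total"] = U[0] + U[1] + U[2] + U[3] + U[4],
    _["forces"] = vec_to_mat(f));
}

// [[Rcpp::export]]
List cg_engine_minimize(NumericMatrix pos, List inp, NumericVector box,
                        int max_steps, double f_tol, double step0) {
  Engine eng;
  eng.init(inp, box);
  std::vector<double> p = mat_to_vec(pos), f(p.size()), ptrial(p.size());
  std::vector<double> ftrial(p.size());
  double U[5], Ut[5];
  eng.eval(p, f, U);
  double e = U[0] + U[1] + U[2] + U[3] + U[4];
  if (!std::isfinite(e)) stop("non-finite energy at minimization start");
  double h = step0;
  int steps = 0;
  double fmax = 0;
  for (steps = 0; steps < max_steps; ++steps) {
    fmax = 0;
    for (size_t q = 0; q < f.size(); ++q)
      fmax = std::max(fmax, std::fabs(f[q]));
    if (fmax < f_tol) break;
    // steepest descent, displacement capped at h along the max component
    double scale = h / fmax;
    for (size_t q = 0; q < p.size(); ++q)
      ptrial[q] = p[q] + scale * f[q];
    eng.eval(ptrial, ftrial, Ut);
    double et = Ut[0] + Ut[1] + Ut[2] + Ut[3] + Ut[4];
    if (et <= e) {
      p.swap(ptrial); f.swap(ftrial); e = et;
      for (int q = 0; q < 5; ++q) U[q] = Ut[q];
      h = std::min(h * 1.2, 0.05);
    } else {
      h *= 0.5;
      if (h < 1e-8) break;
    }
  }
  return List::create(_["pos"] = vec_to_mat(p), _["energy"] = e,
                      _["steps"] = steps, _["fmax"] = fmax,
                      _["converged"] = fmax < f_tol);
}

// [[Rcpp::export]]
List cg_engine_run(NumericMatrix pos, NumericMatrix vel, List inp,
                   NumericVector box, double dt, int nsteps,
                   double T0, double tau, int stride) {
  Engine eng;
  eng.init(inp, box);
  int n = pos.nrow();
  std::vector<double> p = mat_to_vec(pos), v = mat_to_vec(vel),
    f(3 * n);
  double U[5];
  eng.eval(p, f, U);

  int ndf = 3 * n - 3;
  int nfr = nsteps / stride + 1;
  NumericVector traj(nfr * n * 3);
  NumericVector times(nfr), epot(nfr), ekin(nfr), temp(nfr);
  NumericMatrix ecomp(nfr, 5);

  int fr = 0;
  for (int step = 0; step <= nsteps; ++step) {
    if (step % stride == 0) {
      double ke = 0;
      for (int q = 0; q < n; ++q)
        ke += 0.5 * eng.mass[q] * (v[3*q]*v[3*q] + v[3*q+1]*v[3*q+1] +
                                   v[3*q+2]*v[3*q+2]);
      times[fr] = step * dt;
      epot[fr] = U[0] + U[1] + U[2] + U[3] + U[4];
      ekin[fr] = ke;
      temp[fr] = 2.0 * ke / (ndf * KB);
      for (int c = 0; c < 5; ++c) ecomp(fr, c) = U[c];
      for (int q = 0; q < n; ++q) {
        traj[fr + nfr * (q + (long)n * 0)] = p[3*q];
        traj[fr + nfr * (q + (long)n * 1)] = p[3*q+1];
        traj[fr + nfr * (q + (long)n * 2)] = p[3*q+2];
      }
      ++fr;
    }
    if (step == nsteps) break;

    // velocity Verlet
    for (int q = 0; q < n; ++q) {
      double im = 0.5 * dt / eng.mass[q];
      v[3*q]   += im * f[3*q];
      v[3*q+1] += im * f[3*q+1];
      v[3*q+2] += im * f[3*q+2];
      p[3*q]   += dt * v[3*q];
      p[3*q+1] += dt * v[3*q+1];
      p[3*q+2] += dt * v[3*q+2];
    }
    for (int q = 0; q < 3 * n; ++q)
      if (!std::isfinite(p[q]))
        stop("simulation blow-up: non-finite coordinate at step %d",
             step + 1);
    eng.eval(p, f, U);
    double ke = 0;
    for (int q = 0; q < n; ++q) {
      double im = 0.5 * dt / eng.mass[q];
      v[3*q]   += im * f[3*q];
      v[3*q+1] += im * f[3*q+1];
      v[3*q+2] += im * f[3*q+2];
      ke += 0.5 * eng.mass[q] * (v[3*q]*v[3*q] + v[3*q+1]*v[3*q+1] +
                                 v[3*q+2]*v[3*q+2]);
    }
    if (tau > 0) {   // Berendsen weak-coupling rescale
      double Tinst = 2.0 * ke / (ndf * KB);
      if (Tinst > 1e-12) {
        double lam2 = 1.0 + dt / tau * (T0 / Tinst - 1.0);
        double lam = std::sqrt(std::max(0.64, std::min(1.5625, lam2)));
        for (int q = 0; q < 3 * n; ++q) v[q] *= lam;
      }
    }
  }

  traj.attr("dim") = IntegerVector::create(nfr, n, 3);
  return List::create(
    _["trajectory"] = traj, _["times"] = times, _["epot"] = epot,
    _["ekin"] = ekin, _["temperature"] = temp, _["components"] = ecomp,
    _["pos"] = vec_to_mat(p), _["vel"] = vec_to_mat(v));
}
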