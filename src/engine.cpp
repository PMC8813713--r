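// Compartmental network integrator.
//
// Semi-implicit scheme: gating variables advance by exponential Euler using
// rates evaluated at the current voltage; the cable/membrane equation is then
// solved by backward Euler on each cell's tree (Hines elimination, parents
// ordered before children).  Unconditionally stable at dt = 0.025 ms.
//
// Units: mV, ms, nA, uS, nF, um.  uS * mV = nA; nA * um = fAm (dipole).

#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

static const double VMIN = -120.0, VMAX = 70.0, VSTEP = 0.05;
static const int NV = (int)((VMAX - VMIN) / VSTEP) + 1;

// x / (exp(x / y) - 1), singularity-safe (NEURON's vtrap)
static inline double vtrap(double x, double y) {
  if (std::fabs(x / y) < 1e-6) return y * (1.0 - x / (2.0 * y));
  return x / (std::exp(x / y) - 1.0);
}

// Gate ids: 0 m_na, 1 h_na, 2 n_kdr, 3 n_km, 4 m_ca, 5 h_ca,
//           6 m_cat, 7 h_cat, 8 m_ar, 9 n_kca (not table-driven)
static const int NGATE = 10;
static const int NVTAB = 9;

struct Tables {
  // interleaved per voltage index: [inf, rel], rel = 1 - exp(-dt / tau)
  std::vector<double> tab[NVTAB];
};

static void build_tables(Tables &T, double dt, double celsius, double vtraub) {
  const double tadj_hh = std::pow(3.0, (celsius - 36.0) / 10.0);
  const double tadj_m  = std::pow(2.3, (celsius - 23.0) / 10.0); // km/ca (Mainen)
  const double tadj_t  = std::pow(2.3, (celsius - 24.0) / 10.0); // cat
  for (int g = 0; g < NVTAB; ++g) T.tab[g].resize(2 * NV);
  for (int i = 0; i < NV; ++i) {
    double v = VMIN + i * VSTEP;
    double v2 = v - vtraub;
    double a, b, tau, inf;
    auto put = [&](int g, double inf_, double rel_) {
      T.tab[g][2 * i] = inf_; T.tab[g][2 * i + 1] = rel_;
    };
    // hh2 (Traub-like kinetics)
    a = 0.32 * vtrap(13.0 - v2, 4.0);  b = 0.28 * vtrap(v2 - 40.0, 5.0);
    a *= tadj_hh; b *= tadj_hh;
    put(0, a / (a + b), 1.0 - std::exp(-dt * (a + b)));
    a = 0.128 * std::exp((17.0 - v2) / 18.0);
    b = 4.0 / (1.0 + std::exp((40.0 - v2) / 5.0));
    a *= tadj_hh; b *= tadj_hh;
    put(1, a / (a + b), 1.0 - std::exp(-dt * (a + b)));
    a = 0.032 * vtrap(15.0 - v2, 5.0); b = 0.5 * std::exp((10.0 - v2) / 40.0);
    a *= tadj_hh; b *= tadj_hh;
    put(2, a / (a + b), 1.0 - std::exp(-dt * (a + b)));
    // km (Mainen): tha -30, qa 9, Ra = Rb = 0.001
    {
      double x = v + 30.0;
      a = 0.001 * ((std::fabs(x / 9.0) < 1e-6) ? 9.0 + x / 2.0
                                               : x / (1.0 - std::exp(-x / 9.0)));
      b = 0.001 * ((std::fabs(x / 9.0) < 1e-6) ? 9.0 - x / 2.0
                                               : -x / (1.0 - std::exp(x / 9.0)));
      inf = a / (a + b); tau = 1.0 / (tadj_m * (a + b));
      put(3, inf, 1.0 - std::exp(-dt / tau));
    }
    // HVA Ca (Mainen)
    a = 0.055 * vtrap(-27.0 - v, 3.8); b = 0.94 * std::exp((-75.0 - v) / 17.0);
    inf = a / (a + b); tau = 1.0 / (tadj_m * (a + b));
    put(4, inf, 1.0 - std::exp(-dt / tau));
    a = 0.000457 * std::exp((-13.0 - v) / 50.0);
    b = 0.0065 / (std::exp((-v - 15.0) / 28.0) + 1.0);
    inf = a / (a + b); tau = 1.0 / (tadj_m * (a + b));
    put(5, inf, 1.0 - std::exp(-dt / tau));
    // T-type Ca (Huguenard/McCormick-style)
    inf = 1.0 / (1.0 + std::exp(-(v + 57.0) / 6.2));
    tau = (0.612 + 1.0 / (std::exp(-(v + 132.0) / 16.7) +
                          std::exp((v + 16.8) / 18.2))) / tadj_t;
    put(6, inf, 1.0 - std::exp(-dt / tau));
    inf = 1.0 / (1.0 + std::exp((v + 81.0) / 4.0));
    tau = ((v < -81.0) ? std::exp((v + 467.0) / 66.6)
                       : 28.0 + std::exp(-(v + 22.0) / 10.5)) / tadj_t;
    put(7, inf, 1.0 - std::exp(-dt / tau));
    // h-current (anomalous rectifier)
    inf = 1.0 / (1.0 + std::exp((v + 75.0) / 5.5));
    tau = 1.0 / (std::exp(-14.59 - 0.086 * v) + std::exp(-1.87 + 0.0701 * v));
    put(8, inf, 1.0 - std::exp(-dt / tau));
  }
}

struct Ev { int comp, slot; double w; };

// [[Rcpp::export]]
List engine_run(List net, NumericMatrix events, SEXP state0_, double dt,
                int nsteps, int record_every, IntegerVector record_comps,
                NumericMatrix iclamp) {
  // --- unpack network ---------------------------------------------------
  IntegerVector parent_ = net["parent"], cellof_ = net["cell"],
      celltype_ = net["celltype"], layer_ = net["layer"],
      is_pyr_ = net["is_pyr"], soma_ = net["soma"],
      cell_start_ = net["cell_start"], cell_end_ = net["cell_end"];
  NumericVector cap_ = net["cap"], ga_ = net["ga"], dz_ = net["dz"],
      area_ = net["area"], gleak_ = net["gleak"], eleak_ = net["eleak"],
      gna_ = net["gna"], gk_ = net["gk"], gkm_ = net["gkm"],
      gca_ = net["gca"], gkca_ = net["gkca"], gcat_ = net["gcat"],
      gar_ = net["gar"];
  NumericMatrix syn_tau1 = net["syn_tau1"], syn_tau2 = net["syn_tau2"],
      syn_e = net["syn_e"];
  IntegerVector conn_ptr_ = net["conn_ptr"], conn_comp_ = net["conn_comp"],
      conn_slot_ = net["conn_slot"];
  NumericVector conn_w_ = net["conn_w"], conn_delay_ = net["conn_delay"];
  List par = net["params"];
  const double ena = par["ena"], ek = par["ek"], vtraub = par["vtraub"],
      celsius = par["celsius"], mg = par["mg"], cao = par["cao"],
      cainf = par["cainf"], taur_cad = par["taur_cad"],
      thresh = par["spike_threshold"], ear = par["e_h"];

  const int ncomp = parent_.size(), ncell = soma_.size(),
      ntype = syn_tau1.nrow();
  const int *parent = parent_.begin(), *cellof = cellof_.begin(),
      *celltype = celltype_.begin(), *layer = layer_.begin(),
      *is_pyr = is_pyr_.begin(), *soma = soma_.begin(),
      *cell_start = cell_start_.begin(), *cell_end = cell_end_.begin(),
      *conn_ptr = conn_ptr_.begin(), *conn_comp = conn_comp_.begin(),
      *conn_slot = conn_slot_.begin();
  const double *cap = cap_.begin(), *ga = ga_.begin(), *area = area_.begin(),
      *gleak = gleak_.begin(), *eleak = eleak_.begin(), *gna = gna_.begin(),
      *gk = gk_.begin(), *gkm = gkm_.begin(), *gca = gca_.begin(),
      *gkca = gkca_.begin(), *gcat = gcat_.begin(), *gar = gar_.begin(),
      *conn_w = conn_w_.begin(), *conn_delay = conn_delay_.begin();

  const double tadj_m = std::pow(2.3, (celsius - 23.0) / 10.0);
  const double nernst_fac =
      1000.0 * 8.313424 * (273.15 + celsius) / (2.0 * 96485.332); // mV
  const double mg357 = mg / 3.57;

  Tables T; build_tables(T, dt, celsius, vtraub);

  // per (celltype, receptor) double-exponential constants
  std::vector<double> d1(ntype * 4), d2(ntype * 4), fct(ntype * 4),
      erev(ntype * 4);
  for (int c = 0; c < ntype; ++c) for (int r = 0; r < 4; ++r) {
    double t1 = syn_tau1(c, r), t2 = syn_tau2(c, r);
    d1[c * 4 + r] = std::exp(-dt / t1); d2[c * 4 + r] = std::exp(-dt / t2);
    double tp = t1 * t2 / (t2 - t1) * std::log(t2 / t1);
    fct[c * 4 + r] = 1.0 / (std::exp(-tp / t2) - std::exp(-tp / t1));
    erev[c * 4 + r] = syn_e(c, r);
  }
  std::vector<int> cct(ncomp);          // celltype of each compartment
  for (int i = 0; i < ncomp; ++i) cct[i] = celltype[cellof[i]];

  // dipole bookkeeping: pyramidal compartments with a vertical lever arm
  std::vector<int> dpi, dppar, dplay;
  std::vector<double> dpw;
  for (int i = 0; i < ncomp; ++i) {
    int p = parent[i];
    if (p < 0 || dz_[i] == 0.0 || !is_pyr[cellof[i]]) continue;
    dpi.push_back(i); dppar.push_back(p); dplay.push_back(layer[cellof[i]]);
    dpw.push_back(ga[i] * dz_[i]);
  }

  // --- state ------------------------------------------------------------
  const int SLEN = ncomp * (1 + NGATE + 1 + 8);
  std::vector<double> V(ncomp), gate(ncomp * NGATE), cai(ncomp),
      synA(ncomp * 4, 0.0), synB(ncomp * 4, 0.0);
  if (!Rf_isNull(state0_)) {
    NumericVector s0(state0_);
    if (s0.size() != SLEN) stop("state vector has wrong length");
    int k = 0;
    for (int i = 0; i < ncomp; ++i) V[i] = s0[k++];
    for (int i = 0; i < ncomp * NGATE; ++i) gate[i] = s0[k++];
    for (int i = 0; i < ncomp; ++i) cai[i] = s0[k++];
    for (int i = 0; i < ncomp * 4; ++i) synA[i] = s0[k++];
    for (int i = 0; i < ncomp * 4; ++i) synB[i] = s0[k++];
  } else {
    for (int i = 0; i < ncomp; ++i) {
      double v = eleak_[i]; V[i] = v;
      int iv = (int)((v - VMIN) / VSTEP);
      double w = (v - (VMIN + iv * VSTEP)) / VSTEP;
      for (int g = 0; g < NVTAB; ++g)
        gate[i * NGATE + g] =
            T.tab[g][2 * iv] * (1 - w) + T.tab[g][2 * iv + 2] * w;
      double a = 0.01 * cainf, b = 0.02;
      gate[i * NGATE + 9] = a / (a + b);
      cai[i] = cainf;
    }
  }

  // --- event buckets ----------------------------------------------------
  std::vector< std::vector<Ev> > bucket(nsteps + 1);
  for (int e = 0; e < events.nrow(); ++e) {
    int s = (int)events(e, 0);
    if (s < 0 || s > nsteps) continue;
    Ev ev; ev.comp = (int)events(e, 1); ev.slot = (int)events(e, 2);
    ev.w = events(e, 3);
    bucket[s].push_back(ev);
  }

  // --- recording --------------------------------------------------------
  const int nrec = nsteps / record_every + 1;
  NumericMatrix dip(nrec, 2);
  NumericVector tout(nrec);
  const int nrc = record_comps.size();
  NumericMatrix vrec(nrc > 0 ? nrec : 1, nrc > 0 ? nrc : 1);
  NumericMatrix isynrec(nrc > 0 ? nrec : 1, nrc > 0 ? nrc : 1);
  std::vector<int> recslot(ncomp, -1);
  for (int j = 0; j < nrc; ++j) recslot[record_comps[j]] = j;
  std::vector<int> spike_cell; std::vector<double> spike_t;
  std::vector<double> prevsoma(ncell);
  for (int c = 0; c < ncell; ++c) prevsoma[c] = V[soma[c]];

  std::vector<double> diag(ncomp), rhs(ncomp), isyn_now(nrc > 0 ? nrc : 1, 0.0);

  auto record_dipole = [&](int ri) {
    double q0 = 0.0, q1 = 0.0;
    for (size_t k = 0; k < dpi.size(); ++k) {
      double c = dpw[k] * (V[dppar[k]] - V[dpi[k]]);
      if (dplay[k] == 0) q0 += c; else q1 += c;
    }
    dip(ri, 0) = q0; dip(ri, 1) = q1;
  };
  record_dipole(0); tout[0] = 0.0;
  for (int j = 0; j < nrc; ++j) { vrec(0, j) = V[record_comps[j]]; isynrec(0, j) = 0.0; }

  const int nicl = iclamp.nrow();

  // --- main loop --------------------------------------------------------
  for (int step = 1; step <= nsteps; ++step) {
    const double tnow = step * dt;
    // synaptic decay + events
    for (int i = 0; i < ncomp; ++i) {
      const double *dd1 = &d1[cct[i] * 4], *dd2 = &d2[cct[i] * 4];
      double *A = &synA[i * 4], *B = &synB[i * 4];
      A[0] *= dd1[0]; A[1] *= dd1[1]; A[2] *= dd1[2]; A[3] *= dd1[3];
      B[0] *= dd2[0]; B[1] *= dd2[1]; B[2] *= dd2[2]; B[3] *= dd2[3];
    }
    for (size_t e = 0; e < bucket[step].size(); ++e) {
      const Ev &ev = bucket[step][e];
      double wf = ev.w * fct[cct[ev.comp] * 4 + ev.slot];
      synA[ev.comp * 4 + ev.slot] += wf;
      synB[ev.comp * 4 + ev.slot] += wf;
    }
    for (int j = 0; j < nrc; ++j) isyn_now[j] = 0.0;

    // membrane assembly
    for (int i = 0; i < ncomp; ++i) {
      double v = V[i];
      if (!std::isfinite(v))
        stop("non-finite membrane potential at t = %f ms (compartment %d)",
             tnow, i + 1);
      double vc = v < VMIN ? VMIN : (v > VMAX - VSTEP ? VMAX - VSTEP : v);
      int iv = (int)((vc - VMIN) / VSTEP);
      double w = (vc - (VMIN + iv * VSTEP)) / VSTEP;
      double *g = &gate[i * NGATE];
      double G = gleak[i], GE = gleak[i] * eleak[i];
      auto gl = [&](int gg) {
        const double *t = &T.tab[gg][2 * iv];
        double inf = t[0] * (1 - w) + t[2] * w;
        double rel = t[1] * (1 - w) + t[3] * w;
        g[gg] += rel * (inf - g[gg]);
      };
      if (gna[i] > 0.0) {
        gl(0); gl(1);
        double gg = gna[i] * g[0] * g[0] * g[0] * g[1];
        G += gg; GE += gg * ena;
      }
      if (gk[i] > 0.0) {
        gl(2);
        double gg = gk[i] * g[2] * g[2] * g[2] * g[2];
        G += gg; GE += gg * ek;
      }
      if (gkm[i] > 0.0) {
        gl(3);
        double gg = gkm[i] * g[3];
        G += gg; GE += gg * ek;
      }
      if (gca[i] > 0.0 || gcat[i] > 0.0) {
        double eca = nernst_fac * std::log(cao / cai[i]);
        double ica = 0.0;
        if (gca[i] > 0.0) {
          gl(4); gl(5);
          double gg = gca[i] * g[4] * g[4] * g[5];
          G += gg; GE += gg * eca;
          ica += gg * (v - eca);
        }
        if (gcat[i] > 0.0) {
          gl(6); gl(7);
          double gg = gcat[i] * g[6] * g[6] * g[7];
          G += gg; GE += gg * eca;
          ica += gg * (v - eca);
        }
        // calcium pool: ica (nA) -> mA/cm2 = 100 * nA / um2; 0.1 um shell
        double drive = -0.51820 * 100.0 * ica / area[i];
        cai[i] += dt * (drive + (cainf - cai[i]) / taur_cad);
        if (cai[i] < 1e-8) cai[i] = 1e-8;
        if (gkca[i] > 0.0) {
          double a = 0.01 * cai[i], b = 0.02;
          double inf = a / (a + b);
          double rel = 1.0 - std::exp(-dt * tadj_m * (a + b));
          g[9] += rel * (inf - g[9]);
          double gg = gkca[i] * g[9];
          G += gg; GE += gg * ek;
        }
      }
      if (gar[i] > 0.0) {
        gl(8);
        double gg = gar[i] * g[8];
        G += gg; GE += gg * ear;
      }
      // synapses
      const double *A = &synA[i * 4], *B = &synB[i * 4];
      const double *er = &erev[cct[i] * 4];
      double gs;
      if ((gs = B[0] - A[0]) > 0.0) {
        G += gs; GE += gs * er[0];
        if (recslot[i] >= 0) isyn_now[recslot[i]] += gs * (v - er[0]);
      }
      if ((gs = B[1] - A[1]) > 0.0) { // NMDA Mg block
        gs /= 1.0 + std::exp(-0.062 * v) * mg357;
        G += gs; GE += gs * er[1];
        if (recslot[i] >= 0) isyn_now[recslot[i]] += gs * (v - er[1]);
      }
      if ((gs = B[2] - A[2]) > 0.0) {
        G += gs; GE += gs * er[2];
        if (recslot[i] >= 0) isyn_now[recslot[i]] += gs * (v - er[2]);
      }
      if ((gs = B[3] - A[3]) > 0.0) {
        G += gs; GE += gs * er[3];
        if (recslot[i] >= 0) isyn_now[recslot[i]] += gs * (v - er[3]);
      }
      diag[i] = cap[i] / dt + G;
      rhs[i] = cap[i] / dt * v + GE;
    }

    // current injections
    for (int q = 0; q < nicl; ++q) {
      if (step >= (int)iclamp(q, 2) && step <= (int)iclamp(q, 3))
        rhs[(int)iclamp(q, 0)] += iclamp(q, 1);
    }

    // axial terms + Hines solve per cell
    for (int i = 0; i < ncomp; ++i) {
      int p = parent[i];
      if (p >= 0) { diag[i] += ga[i]; diag[p] += ga[i]; }
    }
    for (int c = 0; c < ncell; ++c) {
      const int s0 = cell_start[c], s1 = cell_end[c];
      for (int i = s1; i > s0; --i) {
        int p = parent[i];
        double f = ga[i] / diag[i];
        diag[p] -= ga[i] * f;
        rhs[p] += rhs[i] * f;
      }
      V[s0] = rhs[s0] / diag[s0];
      for (int i = s0 + 1; i <= s1; ++i)
        V[i] = (rhs[i] + ga[i] * V[parent[i]]) / diag[i];
      // spike detection at the soma
      double vs = V[soma[c]];
      if (vs >= thresh && prevsoma[c] < thresh) {
        spike_cell.push_back(c); spike_t.push_back(tnow);
        for (int k = conn_ptr[c]; k < conn_ptr[c + 1]; ++k) {
          int ds = (int)std::lround(conn_delay[k] / dt);
          int s = step + (ds < 1 ? 1 : ds);
          if (s <= nsteps) {
            Ev ev; ev.comp = conn_comp[k]; ev.slot = conn_slot[k];
            ev.w = conn_w[k];
            bucket[s].push_back(ev);
          }
        }
      }
      prevsoma[c] = vs;
    }

    if (step % record_every == 0) {
      int ri = step / record_every;
      tout[ri] = tnow;
      record_dipole(ri);
      for (int j = 0; j < nrc; ++j) {
        vrec(ri, j) = V[record_comps[j]];
        isynrec(ri, j) = isyn_now[j];
      }
    }
  }

  // --- pack state -------------------------------------------------------
  NumericVector stateOut(SLEN);
  {
    int k = 0;
    for (int i = 0; i < ncomp; ++i) stateOut[k++] = V[i];
    for (int i = 0; i < ncomp * NGATE; ++i) stateOut[k++] = gate[i];
    for (int i = 0; i < ncomp; ++i) stateOut[k++] = cai[i];
    for (int i = 0; i < ncomp * 4; ++i) stateOut[k++] = synA[i];
    for (int i = 0; i < ncomp * 4; ++i) stateOut[k++] = synB[i];
  }
  return List::create(_["t"] = tout, _["dipole"] = dip,
                      _["spike_cell"] = wrap(spike_cell),
                      _["spike_time"] = wrap(spike_t),
                      _["v"] = vrec, _["isyn"] = isynrec,
                      _["state"] = stateOut);
}
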