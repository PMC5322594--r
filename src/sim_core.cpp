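#include <Rcpp.h>
using namespace Rcpp;

// Daily two-species stage-structured update, identical in arithmetic (and in
// the order of operations) to the pure-R reference stepper `step_daily()`.
// Forcing column layout must match FORCING_NAMES in R/population_model.R:
//  0 alb_dE  1 alb_dL  2 alb_dP  3 alb_muE  4 alb_muL  5 alb_muP  6 alb_muA
//  7 alb_fec 8 alb_diap 9 alb_trigger
// 10 pip_dE 11 pip_dL 12 pip_dP 13 pip_muE 14 pip_muL 15 pip_muP 16 pip_muA
// 17 pip_fec 18 pip_diap 19 pip_trigger
// 20 comp_on

// [[Rcpp::export]]
NumericMatrix sim_core_cpp(NumericMatrix forcing, NumericVector init,
                           double rho_alb, double rho_pip, double cc,
                           double hatch_alb, double hatch_pip) {
  const int n = forcing.nrow();
  if (init.size() != 10) stop("init must have length 10");
  for (int i = 0; i < 10; ++i) {
    if (!R_finite(init[i]) || init[i] < 0) stop("invalid initial state");
  }
  NumericMatrix out(n, 10);
  double aE = init[0], aEd = init[1], aL = init[2], aP = init[3], aA = init[4];
  double pE = init[5], pL = init[6], pP = init[7], pA = init[8], pAd = init[9];

  for (int d = 0; d < n; ++d) {
    const double alb_dE = forcing(d, 0), alb_dL = forcing(d, 1),
                 alb_dP = forcing(d, 2), alb_muE = forcing(d, 3),
                 alb_muL = forcing(d, 4), alb_muP = forcing(d, 5),
                 alb_muA = forcing(d, 6), alb_fec = forcing(d, 7),
                 alb_diap = forcing(d, 8), alb_trig = forcing(d, 9);
    const double pip_dE = forcing(d, 10), pip_dL = forcing(d, 11),
                 pip_dP = forcing(d, 12), pip_muE = forcing(d, 13),
                 pip_muL = forcing(d, 14), pip_muP = forcing(d, 15),
                 pip_muA = forcing(d, 16), pip_fec = forcing(d, 17),
                 pip_diap = forcing(d, 18), pip_trig = forcing(d, 19);
    const double comp_on = forcing(d, 20);

    // albopictus
    double rE = alb_dE + alb_muE;
    double outE = (rE > 0) ? aE * (1.0 - std::exp(-rE)) : 0.0;
    double E_stay = aE - outE;
    double E_dev = (rE > 0) ? outE * alb_dE / rE : 0.0;

    double h = (alb_trig > 0) ? hatch_alb : 0.0;
    double outEd = (h > 0) ? aEd * (1.0 - std::exp(-h)) : 0.0;
    double Ed_stay = aEd - outEd;

    double muL_tot = alb_muL + rho_alb * aL;
    double rL = alb_dL + muL_tot;
    double outL = (rL > 0) ? aL * (1.0 - std::exp(-rL)) : 0.0;
    double L_stay = aL - outL;
    double L_dev = (rL > 0) ? outL * alb_dL / rL : 0.0;

    double rP = alb_dP + alb_muP;
    double outP = (rP > 0) ? aP * (1.0 - std::exp(-rP)) : 0.0;
    double P_stay = aP - outP;
    double P_dev = (rP > 0) ? outP * alb_dP / rP : 0.0;

    double eggs_alb = alb_fec * aA;
    double n_aE = E_stay + (1.0 - alb_diap) * eggs_alb;
    double n_aEd = Ed_stay + alb_diap * eggs_alb;
    double n_aL = L_stay + E_dev + outEd;
    double n_aP = P_stay + L_dev;
    double n_aA = aA * std::exp(-alb_muA) + P_dev;

    // pipiens (competition uses beginning-of-day albopictus larvae)
    double comp = (comp_on > 0) ? cc * aL : 0.0;

    double rEp = pip_dE + pip_muE;
    double outEp = (rEp > 0) ? pE * (1.0 - std::exp(-rEp)) : 0.0;
    double Ep_stay = pE - outEp;
    double Ep_dev = (rEp > 0) ? outEp * pip_dE / rEp : 0.0;

    double muLp_tot = pip_muL + rho_pip * pL + comp;
    double rLp = pip_dL + muLp_tot;
    double outLp = (rLp > 0) ? pL * (1.0 - std::exp(-rLp)) : 0.0;
    double Lp_stay = pL - outLp;
    double Lp_dev = (rLp > 0) ? outLp * pip_dL / rLp : 0.0;

    double rPp = pip_dP + pip_muP;
    double outPp = (rPp > 0) ? pP * (1.0 - std::exp(-rPp)) : 0.0;
    double Pp_stay = pP - outPp;
    double Pp_dev = (rPp > 0) ? outPp * pip_dP / rPp : 0.0;

    double hp = (pip_trig > 0) ? hatch_pip : 0.0;
    double outAd = (hp > 0) ? pAd * (1.0 - std::exp(-hp)) : 0.0;
    double Ad_stay = pAd - outAd;

    double em = Pp_dev;
    double n_pE = Ep_stay + pip_fec * pA;
    double n_pL = Lp_stay + Ep_dev;
    double n_pP = Pp_stay + Lp_dev;
    double n_pA = pA * std::exp(-pip_muA) + (1.0 - pip_diap) * em + outAd;
    double n_pAd = Ad_stay + pip_diap * em;

    aE = n_aE; aEd = n_aEd; aL = n_aL; aP = n_aP; aA = n_aA;
    pE = n_pE; pL = n_pL; pP = n_pP; pA = n_pA; pAd = n_pAd;

    out(d, 0) = aE; out(d, 1) = aEd; out(d, 2) = aL; out(d, 3) = aP;
    out(d, 4) = aA; out(d, 5) = pE; out(d, 6) = pL; out(d, 7) = pP;
    out(d, 8) = pA; out(d, 9) = pAd;
  }
  return out;
}
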