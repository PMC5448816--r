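/* Minimal GLPK bridge: one dense-in/triplet-matrix LP solve per call.
 *
 * Bounds use +-Inf sentinels; a row/column with lb == ub becomes a fixed
 * (equality) constraint.  Solutions are reported with GLPK's basic-solution
 * status mapped to a small status vocabulary used by the R layer.
 */
#include <math.h>
#include <glpk.h>
#include <R.h>
#include <Rinternals.h>
#include <R_ext/Rdynload.h>

static void set_bounds(glp_prob *lp, int is_row, int idx, double lb, double ub)
{
    int type;
    if (!R_FINITE(lb) && !R_FINITE(ub))      type = GLP_FR;
    else if (!R_FINITE(lb))                  type = GLP_UP;
    else if (!R_FINITE(ub))                  type = GLP_LO;
    else if (lb == ub)                       type = GLP_FX;
    else                                     type = GLP_DB;
    if (is_row)
        glp_set_row_bnds(lp, idx, type, lb, ub);
    else
        glp_set_col_bnds(lp, idx, type, lb, ub);
}

SEXP C_glpk_solve(SEXP col_lb, SEXP col_ub, SEXP obj, SEXP maximize,
                  SEXP row_lb, SEXP row_ub,
                  SEXP ia, SEXP ja, SEXP ar)
{
    const int ncol = LENGTH(col_lb);
    const int nrow = LENGTH(row_lb);
    const int nnz  = LENGTH(ar);
    const double *clb = REAL(col_lb), *cub = REAL(col_ub), *cobj = REAL(obj);
    const double *rlb = REAL(row_lb), *rub = REAL(row_ub);
    const int *pi = INTEGER(ia), *pj = INTEGER(ja);
    const double *pa = REAL(ar);
    int j, i, rc, st;

    glp_term_out(GLP_OFF);
    glp_prob *lp = glp_create_prob();
    glp_set_obj_dir(lp, asLogical(maximize) ? GLP_MAX : GLP_MIN);
    glp_add_cols(lp, ncol);
    for (j = 1; j <= ncol; j++) {
        set_bounds(lp, 0, j, clb[j - 1], cub[j - 1]);
        glp_set_obj_coef(lp, j, cobj[j - 1]);
    }
    if (nrow > 0) {
        glp_add_rows(lp, nrow);
        for (i = 1; i <= nrow; i++)
            set_bounds(lp, 1, i, rlb[i - 1], rub[i - 1]);
    }
    if (nnz > 0) {
        /* GLPK wants 1-based arrays with element 0 unused */
        int    *gi = (int *)    R_alloc((size_t) nnz + 1, sizeof(int));
        int    *gj = (int *)    R_alloc((size_t) nnz + 1, sizeof(int));
        double *ga = (double *) R_alloc((size_t) nnz + 1, sizeof(double));
        for (i = 0; i < nnz; i++) {
            gi[i + 1] = pi[i];
            gj[i + 1] = pj[i];
            ga[i + 1] = pa[i];
        }
        glp_load_matrix(lp, nnz, gi, gj, ga);
    }

    glp_smcp parm;
    glp_init_smcp(&parm);
    parm.msg_lev = GLP_MSG_OFF;
    /* hard iteration cap: the primal simplex can cycle on degenerate
     * problems; any genuine solve of these models needs far fewer pivots */
    parm.it_lim = 200000;
    rc = glp_simplex(lp, &parm);
    if (rc != 0) {
        /* numerical trouble or cycling: retry from scratch with the
         * presolver and the dual simplex */
        glp_std_basis(lp);
        parm.presolve = GLP_ON;
        parm.meth = GLP_DUALP;
        rc = glp_simplex(lp, &parm);
    }
    st = glp_get_status(lp);

    const char *status;
    if (rc == GLP_ENOPFS)       status = "infeasible";
    else if (rc == GLP_ENODFS)  status = "unbounded";
    else if (rc != 0)           status = "failed";
    else switch (st) {
        case GLP_OPT:    status = "optimal";    break;
        case GLP_NOFEAS: status = "infeasible"; break;
        case GLP_UNBND:  status = "unbounded";  break;
        default:         status = "failed";     break;
    }

    SEXP ans = PROTECT(allocVector(VECSXP, 3));
    SEXP nms = PROTECT(allocVector(STRSXP, 3));
    SET_STRING_ELT(nms, 0, mkChar("status"));
    SET_STRING_ELT(nms, 1, mkChar("objval"));
    SET_STRING_ELT(nms, 2, mkChar("x"));
    setAttrib(ans, R_NamesSymbol, nms);
    SET_VECTOR_ELT(ans, 0, mkString(status));
    SET_VECTOR_ELT(ans, 1, ScalarReal(glp_get_obj_val(lp)));
    SEXP x = PROTECT(allocVector(REALSXP, ncol));
    for (j = 1; j <= ncol; j++)
        REAL(x)[j - 1] = glp_get_col_prim(lp, j);
    SET_VECTOR_ELT(ans, 2, x);
    glp_delete_prob(lp);
    UNPROTECT(3);
    return ans;
}

static const R_CallMethodDef call_entries[] = {
    {"C_glpk_solve", (DL_FUNC) &C_glpk_solve, 9},
    {NULL, NULL, 0}
};

void R_init_steadycom(DllInfo *dll)
{
    R_registerRoutines(dll, NULL, call_entries, NULL, NULL);
    R_useDynamicSymbols(dll, FALSE);
}
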