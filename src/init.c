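#include <R.h>
#include <Rinternals.h>
#include <R_ext/Rdynload.h>

/* deSolve looks the model routines up by name through getNativeSymbolInfo(),
 * so dynamic symbol lookup stays enabled. */
void R_init_relaybounds(DllInfo *dll)
{
    R_useDynamicSymbols(dll, TRUE);
}
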