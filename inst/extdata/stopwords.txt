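a
an
the
and
or
but
of
in
on
at
to
for
with
by
from
as
is
are
was
were
be
been
being
that
this
these
those
it
its
we
our
they
their
he
she
his
her
not
no
nor
also
both
each
other
which
who
whom
what
when
where
while
than
then
so
such
can
could
may
might
will
would
shall
should
do
does
did
have
has
had
into
onto
upon
about
between
among
through
during
further
more
most
some
any
all
only
very
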